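label	year	country	or	ci_low	ci_high	east_asian
DOvidio	2018	Italy	0.30	0.19	0.45	FALSE
Visser	2017	Netherlands	0.77	0.33	1.21	FALSE
Hollinger	2016	USA	0.80	0.53	1.21	FALSE
Mitchell	2015	USA	0.47	0.38	0.58	FALSE
Mariosa	2015	Sweden	0.79	0.68	0.91	FALSE
Seelen	2014	Netherlands	0.72	0.51	1.01	FALSE
Turner	2013	England	0.98	0.85	1.13	FALSE
Kioumourtzoglou	2015	Denmark	0.61	0.46	0.80	FALSE
Moglia	2017	Italy	1.05	0.78	1.42	FALSE
Korner	2012	Germany	1.11	0.76	1.60	FALSE
Armon	1991	USA	1.00	0.29	3.50	FALSE
Sun	2015	China	1.35	1.10	1.67	TRUE
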
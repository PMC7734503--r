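# Country gazetteer: canonical name, aliases, GeoNames id, continent,
# centroid (decimal degrees), bounding box. Centroids and boxes are the
# coarse country-level values used for centroid fallback and offline
# coordinate correction; they are not survey-grade.
country_name	aliases	geoname_id	continent	centroid_lat	centroid_lon	bbox_min_lat	bbox_min_lon	bbox_max_lat	bbox_max_lon
Netherlands	The Netherlands;Holland;NL	2750405	Europe	52.25	5.75	50.75	3.35	53.7	7.25
Germany	Deutschland;DE	2921044	Europe	51.5	10.5	47.27	5.86	55.06	15.04
France	FR	3017382	Europe	46.0	2.0	41.3	-5.15	51.1	9.56
Spain	España;ES	2510769	Europe	40.0	-4.0	35.9	-9.3	43.8	4.35
Italy	Italia;IT	3175395	Europe	42.83	12.83	36.6	6.6	47.1	18.55
United Kingdom	UK;Great Britain;Britain;GB	2635167	Europe	54.75	-2.75	49.9	-8.65	60.9	1.77
Sweden	SE	2661886	Europe	62.0	15.0	55.3	11.0	69.1	24.2
Norway	NO	3144096	Europe	62.0	10.0	57.9	4.6	71.2	31.1
Finland	FI	660013	Europe	64.0	26.0	59.8	20.5	70.1	31.6
Estonia	EE	453733	Europe	59.0	26.0	57.5	21.7	59.7	28.2
Denmark	DK	2623032	Europe	56.0	10.0	54.5	8.0	57.8	15.2
Switzerland	CH	2658434	Europe	47.0	8.0	45.8	5.9	47.8	10.5
Austria	AT	2782113	Europe	47.33	13.33	46.4	9.5	49.0	17.2
Poland	PL	798544	Europe	52.0	20.0	49.0	14.1	54.9	24.2
Czechia	Czech Republic;CZ	3077311	Europe	49.75	15.0	48.5	12.1	51.1	18.9
Portugal	PT	2264397	Europe	39.5	-8.0	36.9	-9.55	42.2	-6.2
Ireland	IE	2963597	Europe	53.0	-8.0	51.4	-10.5	55.4	-5.9
Greece	GR	390903	Europe	39.0	22.0	34.8	19.3	41.8	28.3
Russia	Russian Federation;RU	2017370	Asia	61.52	105.3	41.2	19.6	81.9	180.0
China	PRC;CN	1814991	Asia	35.0	105.0	18.2	73.5	53.6	134.8
Japan	JP	1861060	Asia	36.0	138.0	24.2	122.9	45.5	146.0
India	IN	1269750	Asia	22.0	79.0	6.7	68.1	35.5	97.4
Indonesia	ID	1643084	Asia	-5.0	120.0	-11.0	95.0	6.1	141.0
Malaysia	MY	1733045	Asia	2.5	112.5	0.85	99.6	7.4	119.3
Thailand	TH	1605651	Asia	15.0	100.0	5.6	97.3	20.5	105.6
Vietnam	Viet Nam;VN	1562822	Asia	16.17	107.83	8.6	102.1	23.4	109.5
South Korea	Republic of Korea;Korea;KR	1835841	Asia	36.5	127.75	33.1	124.6	38.6	129.6
Iran	Islamic Republic of Iran;IR	130758	Asia	32.0	53.0	25.1	44.0	39.8	63.3
Turkey	Türkiye;TR	298795	Asia	39.0	35.0	35.8	26.0	42.1	44.8
Israel	IL	294640	Asia	31.5	34.75	29.5	34.27	33.3	35.9
United States	USA;US;United States of America	6252001	North America	39.76	-98.5	18.9	-179.2	71.4	-66.9
Canada	CA	6251999	North America	60.0	-96.0	41.7	-141.0	83.1	-52.6
Mexico	MX	3996063	North America	23.0	-102.0	14.5	-118.4	32.7	-86.7
Panama	PA	3703430	North America	9.0	-80.0	7.2	-83.0	9.65	-77.2
Costa Rica	CR	3624060	North America	10.0	-84.0	8.0	-85.95	11.2	-82.5
Brazil	BR	3469034	South America	-10.0	-55.0	-33.75	-73.99	5.27	-34.8
Argentina	AR	3865483	South America	-34.0	-64.0	-55.1	-73.6	-21.8	-53.6
Chile	CL	3895114	South America	-35.68	-71.54	-55.9	-75.7	-17.5	-66.4
Peru	PE	3932488	South America	-10.0	-76.0	-18.35	-81.3	-0.04	-68.7
Ecuador	EC	3658394	South America	-2.0	-77.5	-5.0	-92.0	1.4	-75.2
Colombia	CO	3686110	South America	4.0	-72.0	-4.2	-79.0	12.5	-66.9
Australia	AU	2077456	Oceania	-25.0	135.0	-43.6	112.9	-10.7	153.6
New Zealand	NZ;Aotearoa	2186224	Oceania	-42.0	174.0	-47.3	166.5	-34.4	178.6
Papua New Guinea	PNG;PG	2088628	Oceania	-6.0	147.0	-11.7	140.8	-1.3	155.96
South Africa	ZA	953987	Africa	-29.0	24.0	-34.8	16.5	-22.1	32.9
Kenya	KE	192950	Africa	1.0	38.0	-4.7	33.9	5.5	41.9
Tanzania	United Republic of Tanzania;TZ	149590	Africa	-6.0	35.0	-11.75	29.3	-0.98	40.4
Ethiopia	ET	337996	Africa	8.0	38.0	3.4	33.0	14.9	48.0
Madagascar	MG	1062947	Africa	-20.0	47.0	-25.6	43.2	-11.9	50.5
Cameroon	CM	2233387	Africa	6.0	12.5	1.65	8.5	13.1	16.2
Antarctica	AQ	6697173	Antarctica	-80.0	0.0	-90.0	-180.0	-60.5	180.0
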
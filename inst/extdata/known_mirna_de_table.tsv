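mirna_id	log2fc	direction	adj_p	location
hsa-miR-934	10.81	up	2.80E-62	chrX:135633037-135633119
hsa-miR-1269a	8.00	up	1.95E-09	chr4:67142542-67142646
hsa-miR-671-5p	7.15	up	1.54E-05	chr7:150935507-150935624
hsa-miR-663a	7.00	up	4.72E-05	chr20:26188822-26188914
hsa-miR-1292	4.72	up	5.30E-22	chr20:2633423-2633488
hsa-miR-615-5p	4.55	up	8.00E-56	chr12:54427734-54427829
hsa-miR-2276	4.50	up	8.08E-07	chr13:24736555-24736643
hsa-miR-1307-3p	3.50	up	0.00E+00	chr10:105154010-105154158
hsa-miR-3654	3.11	up	6.82E-08	chr7:132719620-132719675
hsa-miR-4741	2.70	up	1.98E-04	chr18:20513312-20513401
hsa-miR-100-5p	2.53	up	7.79E-04	chr11:122022937-122023016
hsa-miR-3189-3p	2.53	up	1.23E-06	chr19:18497372-18497444
hsa-miR-548t-5p	2.51	up	6.42E-12	chr4:174189311-174189384
hsa-miR-769-3p	2.25	up	4.12E-09	chr19:46522190-46522307
hsa-miR-1307-5p	2.09	up	1.08E-105	chr10:105154010-105154158
hsa-miR-3687	2.05	up	3.22E-04	chr21:9826203-9826263
hsa-miR-324-5p	2.02	up	1.36E-51	chr17:7126616-7126698
hsa-miR-449c-5p	1.74	up	7.67E-06	chr5:54468090-54468181
hsa-miR-532-5p	1.51	up	3.50E-16	chrX:49767754-49767844
hsa-miR-122-5p	1.35	up	7.26E-04	chr18:56118306-56118390
hsa-miR-301b	1.30	up	1.84E-03	chr22:22007270-22007347
hsa-miR-652-3p	1.23	up	2.34E-13	chrX:109298557-109298654
hsa-miR-181a-5p	1.23	up	0.00E+00	chr1:198828173-198828282
hsa-miR-140-3p	1.18	up	0.00E+00	chr16:69966984-69967083
hsa-miR-331-3p	1.03	up	1.83E-22	chr12:95702196-95702289
hsa-miR-10a-5p	1.00	up	0.00E+00	chr17:46657200-46657309
hsa-miR-3656	-6.94	down	1.44E-05	chr11:118889654-118889722
hsa-miR-146a-5p	-4.58	down	2.48E-06	chr5:159912359-159912457
hsa-miR-1246	-3.64	down	3.18E-292	chr2:177465708-177465780
hsa-miR-143-3p	-3.50	down	3.27E-05	chr5:148808481-148808586
hsa-miR-23a-5p	-2.50	down	4.30E-31	chr19:13947401-13947473
hsa-miR-4508	-2.37	down	1.67E-16	chr15:23807209-23807278
hsa-miR-4488	-2.27	down	3.64E-22	chr11:61276068-61276129
hsa-miR-548o-3p	-2.09	down	2.26E-03	chr7:102046189-102046302
hsa-miR-29c-5p	-2.07	down	9.01E-04	chr1:207975197-207975284
hsa-miR-21-3p	-1.90	down	5.29E-97	chr17:57918627-57918698
hsa-miR-215	-1.85	down	0.00E+00	chr1:220291195-220291304
hsa-miR-139-3p	-1.64	down	3.27E-11	chr11:72326107-72326174
hsa-miR-720	-1.56	down	5.01E-03	chr3:164059129-164059238
hsa-miR-3141	-1.45	down	5.75E-07	chr5:153975572-153975632
hsa-miR-29b-1-5p	-1.43	down	2.20E-07	chr7:130562218-130562298
hsa-miR-141-5p	-1.41	down	9.27E-03	chr12:7073260-7073354
hsa-miR-25-5p	-1.29	down	0.00E+00	chr7:99691183-99691266
hsa-miR-197-5p	-1.27	down	1.24E-08	chr1:110141515-110141589
hsa-miR-1260b	-1.19	down	4.47E-10	chr11:96074602-96074690
hsa-miR-22-5p	-1.17	down	4.87E-14	chr17:1617197-1617281
hsa-miR-628-5p	-1.06	down	1.42E-03	chr15:55665138-55665232
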
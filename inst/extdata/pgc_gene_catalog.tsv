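order	gene	locus_tag	pgc_specific	universal	filtered_length	note
1	hemH	Dshi_3498	FALSE	TRUE	150	Not specific to PGC
2	hyp_3499	Dshi_3499	FALSE	TRUE	150	Not specific to PGC
3	comF	Dshi_3500	FALSE	TRUE	150	Not specific to PGC
4	crtA	Dshi_3501	TRUE	TRUE	150	
5	bchI	Dshi_3502	TRUE	TRUE	150	
6	bchD	Dshi_3503	TRUE	TRUE	150	
7	bchO	Dshi_3504	TRUE	TRUE	150	
8	hyp_3505	Dshi_3505	FALSE	TRUE	150	Not specific to PGC
9	hyp_3506	Dshi_3506	FALSE	TRUE	150	Not specific to PGC
10	grxC	Dshi_3507	FALSE	TRUE	150	Not specific to PGC
11	crtI	Dshi_3508	TRUE	TRUE	150	
12	crtB	Dshi_3509	TRUE	TRUE	150	
13	tspO	Dshi_3510	TRUE	TRUE	150	
14	hyp_3511	Dshi_3511	FALSE	TRUE	150	Not specific to PGC
15	crtC	Dshi_3512	TRUE	TRUE	150	
16	crtD	Dshi_3513	TRUE	TRUE	150	
17	crtE	Dshi_3514	TRUE	TRUE	150	
18	crtF	Dshi_3515	TRUE	TRUE	150	
19	bchC	Dshi_3516	TRUE	TRUE	150	
20	bchX	Dshi_3517	TRUE	TRUE	150	
21	bchY	Dshi_3518	TRUE	TRUE	150	
22	bchZ	Dshi_3519	TRUE	TRUE	150	
23	pufQ	Dshi_3520	TRUE	TRUE	50	<100 amino acids
24	pufB	Dshi_3521	TRUE	TRUE	50	<100 amino acids
25	pufA	Dshi_3522	TRUE	TRUE	50	<100 amino acids
26	pufL	Dshi_3523	TRUE	TRUE	150	
27	pufM	Dshi_3524	TRUE	TRUE	150	
28	pufC	Dshi_3525	TRUE	FALSE	150	in some species alternated with PufX
29	dxps	Dshi_3526	TRUE	TRUE	150	
30	idi	Dshi_3527	TRUE	TRUE	50	<100 amino acids
31	bchP	Dshi_3528	TRUE	TRUE	150	
32	pucC2	Dshi_3529	TRUE	TRUE	150	
33	bchG	Dshi_3530	TRUE	TRUE	150	
34	ppsR	Dshi_3531	TRUE	TRUE	150	
35	ppaA	Dshi_3532	TRUE	TRUE	50	<100 amino acids
36	bchF	Dshi_3533	TRUE	TRUE	150	
37	bchN	Dshi_3534	TRUE	TRUE	150	
38	bchB	Dshi_3535	TRUE	TRUE	150	
39	bchH	Dshi_3536	TRUE	TRUE	150	
40	bchL	Dshi_3537	TRUE	TRUE	150	
41	bchM	Dshi_3538	TRUE	TRUE	150	
42	lhaA	Dshi_3539	TRUE	TRUE	150	
43	puhA	Dshi_3540	TRUE	TRUE	150	
44	puhB	Dshi_3541	TRUE	TRUE	150	
45	puhC	Dshi_3542	TRUE	TRUE	50	<100 amino acids
46	hyp_3543	Dshi_3543	TRUE	TRUE	50	<100 amino acids
47	acsF	Dshi_3544	TRUE	TRUE	150	
48	puhE	Dshi_3545	TRUE	TRUE	150	
49	hemA	Dshi_3546	FALSE	TRUE	150	Not specific to PGC
50	cycA	Dshi_3547	TRUE	TRUE	50	<100 amino acids
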
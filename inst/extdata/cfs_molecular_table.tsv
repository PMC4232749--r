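fra	chrom	start	end	anchor_from	anchor_to	inducer	frequency	cancer_genes	mirnas	refs	note
FRA1E	chr1	97,749,961	98,119,925	RP4-538N4	RP11-128G13	Aphidicolin	Common			CR92	
FRA1H	chr1	216,110,179	226,742,379	RP11-22M7	RP11-118H4	5-Azacytidine	Common	TGFB2	hsa-mir-215;hsa-mir-194-1;hsa-mir-664a;hsa-mir-320b-2;hsa-mir-4742;hsa-mir-6741	CR154	
FRA2Ccen	chr2	18,524,760	19,272,430	RP11-720L11	RP11-78J22	Aphidicolin	Common			CR97	
FRA2Ctel	chr2	14,934,889	15,681,539	RP11-526G2	RP11-32P22	Aphidicolin	Common			CR97	
FRA2G	chr2	169,498,510	170,313,244	RP11-285F23	RP11-724O16	Aphidicolin	Common			CR155	
FRA2H	chr2	186,716,111	187,251,132	RP11-561J1	RP11-639N24	Aphidicolin	Common			CR156	
FRA3B	chr3	59,623,632	63,846,635	RP11-70P20	RP11-50F24	Aphidicolin	Common			CR157	
FRA4F	chr4	90,208,191	97,312,924	RP11-549C16	RP11-145G20	Aphidicolin	Common			CR109	
FRA6E	chr6	160,275,245	166,079,958	D6S1581	D6S1719	Aphidicolin	Common			CR158	
FRA6F	chr6	111,577,970	112,568,919	RP5-1112D6	RP1-142L7	Aphidicolin	Common			CR159	
FRA6H	chr6	27,804,038	37,156,663	RP1-193B12	RP11-588I14	Aphidicolin	Common	RXRB;PPARD;CDKN1A	hsa-mir-877;hsa-mir-4640;hsa-mir-6891;hsa-mir-6832;hsa-mir-4646;hsa-mir-1236;hsa-mir-6721;hsa-mir-6833;hsa-mir-3135b;hsa-mir-219a-1;hsa-mir-6873;hsa-mir-6834;hsa-mir-5004;hsa-mir-3934;hsa-mir-7159;hsa-mir-1275;hsa-mir-6835;hsa-mir-7111;hsa-mir-5690;hsa-mir-3925	CR115	
FRA7B	chr7	1	12,392,296	Telomere	RP11-507C1	Aphidicolin	Common	PDGFA;RAC1	hsa-mir-339;hsa-mir-4655;hsa-mir-6836;hsa-mir-4648;hsa-mir-4656;hsa-mir-589;hsa-mir-6874;hsa-mir-3683	CR116	
FRA7E	chr7	80,508,751	84,935,939	D7S1934	SHGC-104456	Aphidicolin	Common	HGF		CR117	
FRA7G	chr7	115,894,865	116,072,877	D7S486	D7S522	Aphidicolin	Common			CR160	
FRA7H	chr7	130,413,791	130,857,950	D7S786	D7S649	Aphidicolin	Common		hsa-mir-29a;hsa-mir-29b-1	CR161	
FRA7I	chr7	144,671,106	146,121,417	SHGC-153624s	WSS2627	Aphidicolin	Common			CR120	
FRA7K	chr7	110,657,856	111,031,412	WI-5281	SHGC-78648	Aphidicolin	Common			CR121	
FRA8C	chr8	124,285,269	128,421,245	RP11-468O2	RP11-382A18	Aphidicolin	Common		hsa-mir-548aa-1;hsa-mir-548d-1;hsa-mir-6844;hsa-mir-4662b;hsa-mir-4662a	CR162	
FRA9G	chr9	17,135,038	17,503,917	Within c9orf39/CNTLN		Aphidicolin	Common			CR125	
FRA10F	chr10	125,391,503	128,256,865	RP11-391M7	RP11-179O22	Aphidicolin	Common	CTBP2	hsa-mir-4296;hsa-mir-4484	CR130	
FRA11E	chr11	32,086,458	34,028,916	RP1-17K7	RP13-786C16	Aphidicolin	Common			CR134	
FRA11G	chr11	113,688,799	118,157,704	RP11-667M19	RP11-832A4	Aphidicolin	Common	ZBTB16		CR133	
FRA13A	chr13	35,546,088	36,184,897	RP11-307O13	RP11-270C18	Aphidicolin	Common			CR139	
FRA13E	chr13	73,285,774	76,386,498	RP11-342J4	RP11-29G8	Aphidicolin	Common			CR115	
FRA16D	chr16	78,420,359	78,731,553	AH009490.2	FRA16D seq	Aphidicolin	Common			CR163	
FRAXB	chrX	6,595,111	7,548,235	DXS1130	DXS237	Aphidicolin	Common		hsa-mir-4767	CR164	
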
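# Survey of annotated telomerase-RNA (TER) loci in Saccharomycetaceae.
# Columns: intervals are "start-end", 1-based inclusive, forward-strand
# genomic coordinates regardless of transcript strand; empty cell = feature
# not located. coord_citation is TRUE when the TER coordinates were reported
# in earlier literature (FALSE marks loci first annotated by this survey).
# Normalized typographic fixes relative to the printed source table
# (misplaced thousands commas; both flagged here, not silently):
#   K. marxianus twj  507,518-50,7671 -> 507518-507671
#   S. eubayanus ter  476,134-47,7336 -> 476134-477336
species	accession	strand	ter	ku	template	est1	twj	sm1	coord_citation
K. aestuarii	AEAS01000245.1	neg	16338-17322		16940-16966	16794-16862	16378-16485	16350-16359	TRUE
K. wickerhamii	AEAV01000432.1	pos	250-1327		662-693	765-858	1183-1290	1307-1316	TRUE
K. marxianus	NC_036029.1	pos	506443-507711		506855-506888	506967-507049	507518-507671	507691-507700	TRUE
K. dobzhanskii	CCBQ010000012.1	pos	461805-463090		462224-462257	462337-462499	462905-463051	463070-463079	TRUE
K. lactis	NC_006038.1	pos	611456-612727		611890-611919	612006-612090	612532-612687	612708-612716	TRUE
E. coryli	AZAH01000001.1	neg	269038-270368		269938-269968				FALSE
E. cymbalariae	NC_016454.1	pos	54147-54960		54451-54480				FALSE
E. gossypii	NC_005782.2	neg	677871-679048		678276-678305				TRUE
Ashbya aceri	CP006020.1	neg	693543-694708		693942-693973				FALSE
L. kluyveri	CM000690.1	pos	348600-349844	348876-348930	348957-348982	349129-349208		349825-349833	FALSE
L. lanzarotensis	NW_019212880.1	pos	854162-855236	854389-854444		854754-854820		855217-855225	FALSE
L. waltii	AADM01000270.1	neg	134961-136000	135698-135756	135613-135636	135409-135470		134973-134981	FALSE
L. thermotolerans	NC_013079.1	pos	702500-703549	702730-702791	702853-702876	703022-703083		703530-703538	FALSE
L. dasiensis	LT598456.1	pos	682034-682916	682124-682181	682261-682283			682900-682905	FALSE
L. sp. CBS 6924	LT598470.1	neg	441802-442700	442582-442638		442229-442292		441811-441820	FALSE
L. fermentati	LT598488.1	neg	306329-307150	307076-307129		306786-306850		306339-306348	FALSE
L. meyersii	LT598477.1	pos	575851-576676	575886-575941		576233-576294		576657-576666	FALSE
L. mirantina	LT598468.1	pos	690800-691797			691218-691282		691777-691786	FALSE
L. nothofagi	LT598449.1	pos	388401-389382	388567-388624		388937-389004		389362-389371	FALSE
T. delbrueckii	NC_016504.1	pos	709007-709780	709057-709086		709267-709336		709761-709770	FALSE
T. microellipsoides	FYBL01000005.1	neg	426211-427050	427000-427028		426726-426817		426221-426229	FALSE
Z. bailii	HG316456.1	neg	712655-713400			712902-712974		712665-712673	FALSE
Z. rouxii	NC_012990.1	pos	297087-297883			297527-297616		297865-297873	FALSE
Z. parabailii	CP019499.1	pos	455564-455975			455656-455728		455957-455965	TRUE
T. blattae	NC_020193.1	neg	404150-405050	405003-405033		404650-404733		404165-404173	FALSE
N. castellii	NC_016499.1	pos	381827-383194	382404-382432	382506-382519	382647-382710	382994-383155	383176-383184	TRUE
N. dairenensis	NC_016479.1	neg	1519837-1521377	1520648-1520678	1520550-1520562	1520303-1520369	1519864-1520027	1519849-1519857	FALSE
C. castellii	CAPW01000002.1	neg	272769-274000		273158-273179	272992-273085		272781-272789	FALSE
N. bacillisporus	CAPX01000073.1	pos	1230-2215					2197-2204	FALSE
C. glabrata	NC_006032.2	neg	419194-421150	421007-421081	420914-420932	420657-420852		419206-419214	TRUE
C. bracarensis	CAPU01000044.1	pos	2586-4361		2836-2854			4342-4350	FALSE
N. delphensis	CAPT01000167.1	neg	254761-256469		256151-256169			254773-254781	FALSE
C. nivariensis	CAPV01000033.1	pos	87530-89215		87780-87798			89196-89204	FALSE
S. uvarum	NOWY01000011.1	pos	45720-46940	45996-46050	46193-46203	46301-46377	46703-46848	46921-46929	FALSE
S. eubayanus	NC_030979.1	pos	476134-477336	476392-476446	476588-476598	476694-476770	477100-477240	477317-477325	FALSE
S. arboricola	NC_026172.1	pos	287410-288645	287705-287739	287888-287898	288019-288096	288417-288558	288626-288634	FALSE
S. kudriavzevii	AY639012.1	pos	1-1215	284-320	424-434	585-662	981-1128	1201-1209	TRUE
S. mikatae	AABZ01000048.1	neg	18591-19809	19497-19532	19349-19356	19156-19232	18687-18833	18603-18611	TRUE
S. paradoxus	CP020294.1	pos	307733-308897	308010-308045	308154-308161	308281-308353	308660-308803	308878-308886	TRUE
S. cerevisiae	NC_001134.8	pos	307597-308757	307880-307914	308057-308064	308185-308256	308563-308682	308737-308746	TRUE
S. pastorianus	AZCJ01000004.1	neg	478773-479970	479664-479718	479512-479520	479340-479417	478866-479012	478785-478793	TRUE
S. cer. x S. kud.	AGVY01000004.1	pos	284183-285344	284465-284501	284645-284655	284772-284843	285150-285269	285325-285333	FALSE
S. bayanus	AACG02000058.1	pos	58142-59362	58418-58472	58613-58620	58723-58799	59125-59270	59343-59351	TRUE
S. sp. 'boulardii'	CM003558.1	pos	287536-288696	287818-287854	287998-288008	288124-288195	288502-288621	288677-288685	FALSE
S. sp. M14	MVPU01000005.1	neg	473800-474997	474691-474745	474537-474547	474368-474444	473894-474038	473812-473820	FALSE
S. cariocanus	AY639010.1	pos	1-1163	278-313	424-434	549-621	928-1072	1147-1155	TRUE
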
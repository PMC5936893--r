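#NEXUS
[R-package APE, Mon Sep 21 23:44:35 2026]

BEGIN TAXA;
	DIMENSIONS NTAX = 12;
	TAXLABELS
		lang01
		lang02
		lang03
		lang04
		lang05
		lang06
		lang07
		lang08
		lang09
		lang10
		lang11
		lang12
	;
END;
BEGIN TREES;
	TRANSLATE
		1	lang01,
		2	lang02,
		3	lang03,
		4	lang04,
		5	lang05,
		6	lang06,
		7	lang07,
		8	lang08,
		9	lang09,
		10	lang10,
		11	lang11,
		12	lang12
	;
	TREE * UNTITLED = [&R] (((((11:0.1949390141,8:0.1949390141):0.03650956388,6:0.231448578):0.1585932196,5:0.3900417976):0.5580123638,(((9:0.1963142461,10:0.1963142461):0.06970144415,((2:0.2058286197,12:0.2058286197):0.05618624061,4:0.2620148603):0.004000829979):0.5838440297,(7:0.1790992835,3:0.1790992835):0.6707604365):0.09819444147):0.05194583853,1:1);
	TREE * UNTITLED = [&R] (((((11:0.1536368629,8:0.1536368629):0.03136864285,6:0.1850055058):0.1635797867,5:0.3485852924):0.6048098569,(((9:0.09864195092,10:0.09864195092):0.05330922533,((2:0.09377237418,12:0.09377237418):0.05487250413,4:0.1486448783):0.00330629794):0.6853879782,(7:0.1019010066,3:0.1019010066):0.7354381479):0.1160559949):0.04660485063,1:1);
	TREE * UNTITLED = [&R] (((((11:0.02676028405,8:0.02676028405):0.03507222916,6:0.06183251321):0.1784740635,5:0.2403065767):0.7101024716,(((9:0.04466210894,10:0.04466210894):0.05300752337,((2:0.04446173291,12:0.04446173291):0.04950978484,4:0.09397151775):0.003698114567):0.7461685781,(7:0.1701198351,3:0.1701198351):0.6737183753):0.1065708379):0.0495909517,1:1);
	TREE * UNTITLED = [&R] (((((11:0.1497025545,8:0.1497025545):0.03501798445,6:0.184720539):0.1419433769,5:0.3266639159):0.6300067041,(((9:0.006965707005,10:0.006965707005):0.05581995309,((2:0.009286570726,12:0.009286570726):0.0498474693,4:0.05913404003):0.003651620065):0.7924072517,(7:0.1833608175,3:0.1833608175):0.6718320943):0.1014777082):0.04332937996,1:1);
	TREE * UNTITLED = [&R] (((((11:0.1853280028,8:0.1853280028):0.03823471981,6:0.2235627226):0.1738761714,5:0.397438894):0.5616427673,(((9:0.01222247986,10:0.01222247986):0.05326056873,((2:0.02354483361,12:0.02354483361):0.0386287373,4:0.06217357091):0.003309477681):0.7995057179,(7:0.2448313235,3:0.2448313235):0.620157443):0.09409289484):0.04091833864,1:1);
	TREE * UNTITLED = [&R] (((((11:0.1334837719,8:0.1334837719):0.0395252656,6:0.1730090375):0.1715468402,5:0.3445558777):0.5967473941,(((9:0.1314831014,10:0.1314831014):0.05649686531,((2:0.1258769848,12:0.1258769848):0.05804768306,4:0.1839246679):0.00405529882):0.6621320625,(7:0.1517895818,3:0.1517895818):0.6983224473):0.09119124268):0.05869672815,1:1);
	TREE * UNTITLED = [&R] (((((11:0.08860814162,8:0.08860814162):0.03462970269,6:0.1232378443):0.1619621163,5:0.2851999606):0.6556915673,(((9:0.2205328921,10:0.2205328921):0.05066356658,((2:0.2209741467,12:0.2209741467):0.04631752648,4:0.2672916732):0.00390478544):0.5639421035,(7:0.165159208,3:0.165159208):0.6699793542):0.1057529657):0.05910847211,1:1);
	TREE * UNTITLED = [&R] (((((11:0.215847159,8:0.215847159):0.03176177096,6:0.24760893):0.1565819765,5:0.4041909065):0.5570082828,(((9:0.2043001408,10:0.2043001408):0.04720583136,((2:0.2075158851,12:0.2075158851):0.04100706198,4:0.248522947):0.002983025159):0.6252526603,(7:0.2700499765,3:0.2700499765):0.606708656):0.08444055678):0.03880081067,1:1);
	TREE * UNTITLED = [&R] (((((11:0.1995340572,8:0.1995340572):0.03284593593,6:0.2323799931):0.1421254063,5:0.3745053994):0.5713526912,(((9:0.1488597508,10:0.1488597508):0.05401586526,((2:0.1505345512,12:0.1505345512):0.04892061034,4:0.1994551616):0.003420454504):0.6367834779,(7:0.1103889422,3:0.1103889422):0.7292701517):0.1061989967):0.05414190932,1:1);
	TREE * UNTITLED = [&R] (((((11:0.1505172516,8:0.1505172516):0.03465167417,6:0.1851689258):0.1412912995,5:0.3264602253):0.6230767114,(((9:0.01785098626,10:0.01785098626):0.05287698531,((2:0.007782733372,12:0.007782733372):0.05895089516,4:0.06673362853):0.003994343043):0.7700305907,(7:0.3069561663,3:0.3069561663):0.533802396):0.1087783744):0.05046306334,1:1);
END;
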
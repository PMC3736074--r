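# SentiWordNet v3.0 format fixture (synthetic mini-lexicon)
# POS	ID	PosScore	NegScore	SynsetTerms	Gloss
a	00000001	0.75	0.0	happy#1	synthetic fixture sense for happy
a	00000002	0.625	0.0	hopeful#1	synthetic fixture sense for hopeful
a	00000003	0.75	0.0	grateful#1	synthetic fixture sense for grateful
a	00000004	0.625	0.0	love#1	synthetic fixture sense for love
a	00000005	0.875	0.0	joy#1	synthetic fixture sense for joy
a	00000006	0.625	0.125	blessed#1	synthetic fixture sense for blessed
a	00000007	0.75	0.0	wonderful#1	synthetic fixture sense for wonderful
a	00000008	0.625	0.125	comfort#1	synthetic fixture sense for comfort
a	00000009	0.5	0.125	strength#1	synthetic fixture sense for strength
a	00000010	0.625	0.0	courage#1	synthetic fixture sense for courage
a	00000011	0.75	0.0	thankful#1	synthetic fixture sense for thankful
a	00000012	0.625	0.125	proud#1	synthetic fixture sense for proud
a	00000013	0.625	0.0	confident#1	synthetic fixture sense for confident
a	00000014	0.75	0.0	peaceful#1	synthetic fixture sense for peaceful
a	00000015	0.625	0.0	optimistic#1	synthetic fixture sense for optimistic
a	00000016	0.625	0.0	caring#1	synthetic fixture sense for caring
a	00000017	0.625	0.125	sweet#1	synthetic fixture sense for sweet
a	00000018	0.625	0.0	kind#1	synthetic fixture sense for kind
a	00000019	0.625	0.0	gentle#1	synthetic fixture sense for gentle
a	00000020	0.75	0.0	brave#1	synthetic fixture sense for brave
a	00000021	0.625	0.0	relieved#1	synthetic fixture sense for relieved
a	00000022	0.625	0.0	alive#1	synthetic fixture sense for alive
a	00000023	0.625	0.125	free#1	synthetic fixture sense for free
a	00000024	0.75	0.0	beautiful#1	synthetic fixture sense for beautiful
a	00000025	0.875	0.0	amazing#1	synthetic fixture sense for amazing
a	00000026	0.625	0.0	supportive#1	synthetic fixture sense for supportive
a	00000027	0.75	0.0	encouraging#1	synthetic fixture sense for encouraging
a	00000028	0.625	0.125	healing#1	synthetic fixture sense for healing
a	00000029	0.625	0.0	positive#1	synthetic fixture sense for positive
a	00000030	0.75	0.0	cheerful#1	synthetic fixture sense for cheerful
a	00000031	0.0	0.75	sad#1	synthetic fixture sense for sad
a	00000032	0.0	0.75	scared#1	synthetic fixture sense for scared
a	00000033	0.0	0.625	afraid#1	synthetic fixture sense for afraid
a	00000034	0.0	0.75	lonely#1	synthetic fixture sense for lonely
a	00000035	0.0	0.625	worried#1	synthetic fixture sense for worried
a	00000036	0.125	0.625	tired#1	synthetic fixture sense for tired
a	00000037	0.0	0.75	angry#1	synthetic fixture sense for angry
a	00000038	0.0	0.875	terrible#1	synthetic fixture sense for terrible
a	00000039	0.0	0.875	awful#1	synthetic fixture sense for awful
a	00000040	0.0	0.75	painful#1	synthetic fixture sense for painful
a	00000041	0.0	0.75	depressed#1	synthetic fixture sense for depressed
a	00000042	0.125	0.625	anxious#1	synthetic fixture sense for anxious
a	00000043	0.0	0.625	nervous#1	synthetic fixture sense for nervous
a	00000044	0.125	0.625	tears#1	synthetic fixture sense for tears
a	00000045	0.0	0.875	miserable#1	synthetic fixture sense for miserable
a	00000046	0.0	0.875	devastated#1	synthetic fixture sense for devastated
a	00000047	0.0	0.75	hopeless#1	synthetic fixture sense for hopeless
a	00000048	0.0	0.625	exhausted#1	synthetic fixture sense for exhausted
a	00000049	0.0	0.75	frightened#1	synthetic fixture sense for frightened
a	00000050	0.0	0.625	upset#1	synthetic fixture sense for upset
a	00000051	0.0	0.875	horrible#1	synthetic fixture sense for horrible
a	00000052	0.0	0.75	grief#1	synthetic fixture sense for grief
a	00000053	0.0	0.625	frustrated#1	synthetic fixture sense for frustrated
a	00000054	0.125	0.5	overwhelmed#1	synthetic fixture sense for overwhelmed
n	00000055	0.0	0.0	morning#1	synthetic fixture sense for morning
n	00000056	0.0	0.0	window#1	synthetic fixture sense for window
n	00000057	0.0	0.125	report#1	synthetic fixture sense for report
n	00000058	0.125	0.0	coffee#1	synthetic fixture sense for coffee
n	00000059	0.125	0.0	garden#1	synthetic fixture sense for garden
n	00000060	0.0	0.0	weather#1	synthetic fixture sense for weather
n	00000061	0.0	0.0	kitchen#1	synthetic fixture sense for kitchen
n	00000062	0.125	0.0	travel#1	synthetic fixture sense for travel
n	00000063	0.0	0.0	paper#1	synthetic fixture sense for paper
n	00000064	0.25	0.0	music#1	synthetic fixture sense for music
n	00000065	0.0	0.125	doctor#1	synthetic fixture sense for doctor
n	00000066	0.0	0.25	hospital#1	synthetic fixture sense for hospital
n	00000067	0.0	0.0	week#1	synthetic fixture sense for week
n	00000068	0.25	0.125	family#1	synthetic fixture sense for family
n	00000069	0.25	0.25	normal#1	synthetic fixture sense for normal
n	00000070	0.125	0.375	busy#1	synthetic fixture sense for busy
n	00000071	0.0	0.25	different#1	synthetic fixture sense for different
n	00000072	0.25	0.25	okay#1	synthetic fixture sense for okay
v	00000073	0.5	0.0	happy#2	synthetic fixture second sense for happy
v	00000074	0.75	0.0	love#2	synthetic fixture second sense for love
v	00000075	0.0	0.625	sad#2	synthetic fixture second sense for sad
v	00000076	0.125	0.0	free#2	synthetic fixture second sense for free
v	00000077	0.0	0.125	normal#2	synthetic fixture second sense for normal
a	00000078	0.625	0.25	glad#1 delighted#1	synthetic shared synset
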
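id	name	category	formula	monoisotopic_mass	fragments
S1P	sphingosine-1-phosphate	sphingolipids	C18H38NO5P	379.24875995146	264.2686
C16Cer	Cer(d18:1/16:0)	sphingolipids	C34H67NO3	537.51209501229	264.2686
C17Cer	Cer(d18:1/17:0)	sphingolipids	C35H69NO3	551.52774507643	264.2686
S1P_d7	S1P-d7	sphingolipids		386.29269717192	271.3125
C16Cer_d7	Cer(d18:1-d7/16:0)	sphingolipids		544.55603223275	271.3125
LIP001	synthetic lipid LIP001	fatty acids		280.8468348604	168.5081
LIP002	synthetic lipid LIP002	glycerolipids		253.663397161681	152.1980
LIP003	synthetic lipid LIP003	glycerophospholipids		892.138697471524	535.2832
LIP004	synthetic lipid LIP004	sphingolipids		223.98250278078	134.3895
LIP005	synthetic lipid LIP005	sterols		200.845610866311	120.5074
LIP006	synthetic lipid LIP006	prenols		843.624900523127	506.1749
LIP007	synthetic lipid LIP007	saccharolipids		168.496821318493	101.0981
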
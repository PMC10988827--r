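proband_id	term_id
CVG0005	CP:0000011
CVG0005	CP:0000022
CVG0005	CP:0000037
CVG0005	CP:0000043
LAT0080	CP:0000004
LAT0080	CP:0000005
LAT0080	CP:0000007
LAT0080	CP:0000029
LAT0080	CP:0000033
LAT0080	CP:0000020
LAT0080	CP:0000036
LAT0080	CP:0000043
LAT0022	CP:0000011
LAT0022	CP:0000022
LAT0022	CP:0000043
LAT0045	CP:0000003
LAT0045	CP:0000011
LAT0045	CP:0000022
LAT1696	CP:0000011
LAT1696	CP:0000022
LAT1696	CP:0000036
LAT0123	CP:0000003
LAT0123	CP:0000011
LAT0123	CP:0000027
LAT0123	CP:0000021
LAT1246	CP:0000011
LAT1246	CP:0000022
LAT1246	CP:0000008
LAT0191	CP:0000011
LAT0191	CP:0000027
LAT0191	CP:0000021
LAT0191	CP:0000045
LAT1763	CP:0000004
LAT1763	CP:0000005
LAT1763	CP:0000007
LAT1763	CP:0000012
LAT1763	CP:0000020
LAT1763	CP:0000026
LAT1763	CP:0000037
LAT1763	CP:0000041
CVG0006	CP:0000004
CVG0006	CP:0000005
CVG0006	CP:0000007
CVG0006	CP:0000012
CVG0006	CP:0000020
CVG0006	CP:0000026
CVG0006	CP:0000037
CVG0006	CP:0000043
LAT0108	CP:0000004
LAT0108	CP:0000005
LAT0108	CP:0000007
LAT0108	CP:0000012
LAT0108	CP:0000020
LAT0108	CP:0000026
LAT0108	CP:0000037
LAT0265	CP:0000004
LAT0265	CP:0000005
LAT0265	CP:0000007
LAT0265	CP:0000012
LAT0265	CP:0000020
LAT0265	CP:0000026
LAT0265	CP:0000037
LAT0265	CP:0000041
CVG0001	CP:0000011
CVG0001	CP:0000022
CVG0001	CP:0000036
LAT0040	CP:0000003
LAT0040	CP:0000012
LAT0040	CP:0000017
LAT0201	CP:0000011
LAT0201	CP:0000021
LAT0201	CP:0000008
LAT0248	CP:0000004
LAT0248	CP:0000005
LAT0248	CP:0000007
LAT0248	CP:0000012
LAT0248	CP:0000020
LAT0248	CP:0000028
LAT0248	CP:0000036
LAT0658	CP:0000004
LAT0658	CP:0000005
LAT0658	CP:0000007
LAT0658	CP:0000012
LAT0658	CP:0000033
LAT0658	CP:0000036
LAT0830	CP:0000011
LAT0830	CP:0000020
LAT0830	CP:0000008
LAT0858	CP:0000012
LAT0858	CP:0000017
LAT0858	CP:0000043
LAT1016	CP:0000012
LAT1016	CP:0000017
LAT0909	CP:0000012
LAT0909	CP:0000017
LAT0909	CP:0000041
LAT1028	CP:0000012
LAT1028	CP:0000028
LAT1028	CP:0000021
LAT1391	CP:0000012
LAT1391	CP:0000017
LAT1391	CP:0000043
LAT1617	CP:0000011
LAT1617	CP:0000022
LAT1769	CP:0000011
LAT1769	CP:0000027
LAT1769	CP:0000021
LAT0165	CP:0000004
LAT0165	CP:0000005
LAT0165	CP:0000007
LAT0165	CP:0000012
LAT0165	CP:0000033
LAT0165	CP:0000029
LAT0165	CP:0000036
CVG0003	CP:0000012
CVG0003	CP:0000033
CVG0003	CP:0000021
CVG0003	CP:0000036
LAT0368	CP:0000011
LAT0368	CP:0000022
LAT0368	CP:0000043
LAT0457	CP:0000011
LAT0457	CP:0000022
LAT0457	CP:0000036
LAT1724	CP:0000004
LAT1724	CP:0000005
LAT1724	CP:0000007
LAT1724	CP:0000012
LAT1724	CP:0000020
LAT1724	CP:0000029
LAT0048	CP:0000012
LAT0048	CP:0000017
LAT1415	CP:0000012
LAT1415	CP:0000028
LAT1415	CP:0000030
LAT1415	CP:0000033
LAT1415	CP:0000020
LAT1415	CP:0000048
CVG0007	CP:0000012
CVG0007	CP:0000033
CVG0007	CP:0000020
CVG0007	CP:0000050
CVG0007	CP:0000049
CVG0007	CP:0000048
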
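archetype	term_id
simple_dtga	CP:0000012
simple_dtga	CP:0000017
dorv_dmga	CP:0000012
dorv_dmga	CP:0000033
dorv_dmga	CP:0000020
dorv_dmga	CP:0000030
dorv_dmga	CP:0000048
cctga	CP:0000011
cctga	CP:0000022
cctga	CP:0000037
cctga	CP:0000008
dilv_l	CP:0000011
dilv_l	CP:0000027
dilv_l	CP:0000021
heterotaxy_rai	CP:0000004
heterotaxy_rai	CP:0000005
heterotaxy_rai	CP:0000007
heterotaxy_rai	CP:0000012
heterotaxy_rai	CP:0000020
heterotaxy_rai	CP:0000026
heterotaxy_rai	CP:0000037
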
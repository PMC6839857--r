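sample_id	population	DYS19	DYS389I	DYS389II	DYS390	DYS385
pop1_s001	pop1	14	14	14	15	13-14
pop1_s002	pop1	14	14	14	15	13-14
pop1_s003	pop1	14	14	14	15	13-14
pop1_s004	pop1	14	14	14	15	13-14
pop1_s005	pop1	13	13	14	15	13-14
pop1_s006	pop1	14	14	14	15	13-14
pop1_s007	pop1	14	14	14	15	13-14
pop1_s008	pop1	14	14	14	15	13-14
pop2_s001	pop2	14	14	14	14	13-14
pop2_s002	pop2	14	14	14	14	13-14
pop2_s003	pop2	14	14	14	14	13-14
pop2_s004	pop2	14	14	14	14	13-14
pop2_s005	pop2	14	14	14	14	13-14
pop2_s006	pop2	14	14	14	14	13-15
pop2_s007	pop2	14	14	14	14	13-15
pop2_s008	pop2	14	14	14	14	13-14
pop3_s001	pop3	14	14	14	15	13-14
pop3_s002	pop3	14	13	14	15	13-14
pop3_s003	pop3	14	13	14	15	13-14
pop3_s004	pop3	14	13	14	15	13-14
pop3_s005	pop3	14	13	14	15	13-14
pop3_s006	pop3	14	13	14	15	13-14
pop3_s007	pop3	14	14	14	15	13-14
pop3_s008	pop3	14	13	14	15	13-14
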
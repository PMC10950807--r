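entrez_id	symbol_id	drugbank_approved_targets
1001	SYN1	TRUE
1002	SYN2	TRUE
1003	SYN3	FALSE
1004	SYN4	TRUE
1005	SYN5	TRUE
1006	SYN6	FALSE
1007	SYN7	TRUE
1008	SYN8	TRUE
1009	SYN9	FALSE
1010	SYN10	TRUE
1011	SYN11	TRUE
1012	SYN12	FALSE
1013	SYN13	TRUE
1014	SYN14	TRUE
1015	SYN15	FALSE
1016	SYN16	TRUE
1017	SYN17	TRUE
1018	SYN18	FALSE
1019	SYN19	TRUE
1020	SYN20	TRUE
1021	SYN21	FALSE
1022	SYN22	TRUE
1023	SYN23	TRUE
1024	SYN24	FALSE
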
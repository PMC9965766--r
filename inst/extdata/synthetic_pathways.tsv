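pathway_id	pathway_name	compound	importance
SYN01	synthetic pathway 01	met_034	0.309
SYN01	synthetic pathway 01	met_056	0.818
SYN01	synthetic pathway 01	met_025	0.223
SYN01	synthetic pathway 01	met_016	0.093
SYN01	synthetic pathway 01	met_037	0.989
SYN01	synthetic pathway 01	met_060	0.227
SYN02	synthetic pathway 02	met_012	0.31
SYN02	synthetic pathway 02	met_085	0.835
SYN02	synthetic pathway 02	met_086	0.142
SYN02	synthetic pathway 02	met_062	0.785
SYN02	synthetic pathway 02	met_094	0.709
SYN02	synthetic pathway 02	met_096	0.656
SYN02	synthetic pathway 02	met_099	0.237
SYN02	synthetic pathway 02	met_035	0.812
SYN02	synthetic pathway 02	met_039	0.113
SYN02	synthetic pathway 02	met_045	0.391
SYN03	synthetic pathway 03	met_049	0.891
SYN03	synthetic pathway 03	met_095	0.15
SYN03	synthetic pathway 03	met_040	0.194
SYN03	synthetic pathway 03	met_047	0.429
SYN03	synthetic pathway 03	met_039	0.835
SYN03	synthetic pathway 03	met_006	0.324
SYN04	synthetic pathway 04	met_067	0.329
SYN04	synthetic pathway 04	met_099	0.318
SYN04	synthetic pathway 04	met_082	0.711
SYN04	synthetic pathway 04	met_012	0.882
SYN04	synthetic pathway 04	met_093	0.394
SYN04	synthetic pathway 04	met_003	0.244
SYN04	synthetic pathway 04	met_010	0.912
SYN04	synthetic pathway 04	met_080	0.994
SYN04	synthetic pathway 04	met_090	0.171
SYN04	synthetic pathway 04	met_011	0.741
SYN05	synthetic pathway 05	met_073	0.925
SYN05	synthetic pathway 05	met_060	0.598
SYN05	synthetic pathway 05	met_040	0.31
SYN05	synthetic pathway 05	met_071	0.773
SYN05	synthetic pathway 05	met_008	0.363
SYN05	synthetic pathway 05	met_025	0.334
SYN06	synthetic pathway 06	met_007	0.616
SYN06	synthetic pathway 06	met_081	0.242
SYN06	synthetic pathway 06	met_005	0.738
SYN06	synthetic pathway 06	met_028	0.918
SYN06	synthetic pathway 06	met_082	0.48
SYN06	synthetic pathway 06	met_037	0.218
SYN06	synthetic pathway 06	met_084	0.068
SYN06	synthetic pathway 06	met_027	0.703
SYN07	synthetic pathway 07	met_086	0.735
SYN07	synthetic pathway 07	met_076	0.932
SYN07	synthetic pathway 07	met_046	0.703
SYN07	synthetic pathway 07	met_029	0.61
SYN07	synthetic pathway 07	met_050	0.199
SYN08	synthetic pathway 08	met_033	0.994
SYN08	synthetic pathway 08	met_028	0.903
SYN08	synthetic pathway 08	met_091	0.534
SYN08	synthetic pathway 08	met_092	0.876
SYN08	synthetic pathway 08	met_038	0.851
SYN08	synthetic pathway 08	met_062	0.81
SYN08	synthetic pathway 08	met_021	0.923
SYN08	synthetic pathway 08	met_048	0.95
SYN08	synthetic pathway 08	met_006	0.739
SYN08	synthetic pathway 08	met_014	0.689
SYN08	synthetic pathway 08	met_094	0.779
SYN09	synthetic pathway 09	met_081	0.06
SYN09	synthetic pathway 09	met_075	0.472
SYN09	synthetic pathway 09	met_031	0.495
SYN09	synthetic pathway 09	met_052	0.291
SYN09	synthetic pathway 09	met_059	0.335
SYN09	synthetic pathway 09	met_016	0.226
SYN09	synthetic pathway 09	met_062	0.371
SYN09	synthetic pathway 09	met_047	0.585
SYN09	synthetic pathway 09	met_003	0.639
SYN09	synthetic pathway 09	met_068	0.586
SYN10	synthetic pathway 10	met_071	0.513
SYN10	synthetic pathway 10	met_028	0.829
SYN10	synthetic pathway 10	met_003	0.565
SYN10	synthetic pathway 10	met_092	0.181
SYN10	synthetic pathway 10	met_056	0.993
SYN10	synthetic pathway 10	met_043	0.543
SYN10	synthetic pathway 10	met_021	0.298
SYN11	synthetic pathway 11	met_012	0.966
SYN11	synthetic pathway 11	met_049	0.893
SYN11	synthetic pathway 11	met_033	0.631
SYN11	synthetic pathway 11	met_081	0.773
SYN11	synthetic pathway 11	met_008	0.86
SYN11	synthetic pathway 11	met_018	0.449
SYN11	synthetic pathway 11	met_003	0.134
SYN11	synthetic pathway 11	met_088	0.925
SYN11	synthetic pathway 11	met_037	0.311
SYN11	synthetic pathway 11	met_071	0.906
SYN12	synthetic pathway 12	met_017	0.218
SYN12	synthetic pathway 12	met_008	0.735
SYN12	synthetic pathway 12	met_041	0.54
SYN12	synthetic pathway 12	met_039	0.905
SYN12	synthetic pathway 12	met_013	0.124
SYN12	synthetic pathway 12	met_063	0.232
SYN12	synthetic pathway 12	met_002	0.798
SYN12	synthetic pathway 12	met_014	0.473
SYN12	synthetic pathway 12	met_075	0.638
SYN13	synthetic pathway 13	met_010	0.16
SYN13	synthetic pathway 13	met_008	0.13
SYN13	synthetic pathway 13	met_083	0.648
SYN13	synthetic pathway 13	met_076	0.155
SYN13	synthetic pathway 13	met_071	0.183
SYN13	synthetic pathway 13	met_039	0.218
SYN14	synthetic pathway 14	met_029	0.337
SYN14	synthetic pathway 14	met_068	0.326
SYN14	synthetic pathway 14	met_088	0.495
SYN14	synthetic pathway 14	met_096	0.507
SYN14	synthetic pathway 14	met_055	0.395
SYN14	synthetic pathway 14	met_098	0.769
SYN14	synthetic pathway 14	met_006	0.061
SYN14	synthetic pathway 14	met_058	0.961
SYN15	synthetic pathway 15	met_019	0.418
SYN15	synthetic pathway 15	met_065	0.516
SYN15	synthetic pathway 15	met_017	0.63
SYN15	synthetic pathway 15	met_050	0.558
SYN15	synthetic pathway 15	met_068	0.107
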
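sample	n_total	n_gfp	n_dsred
lung_young_1	20000	850	2938
lung_young_2	20000	852	3020
lung_young_3	20000	851	3022
lung_young_4	20000	808	2986
lung_old_1	20000	261	3083
lung_old_2	20000	245	3013
lung_old_3	20000	276	2965
lung_old_4	20000	306	3007
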
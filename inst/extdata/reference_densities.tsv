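region	compartment	day	mean	sd	n
wound_bed	epidermis	0	0.64	0.21	3
wound_bed	epidermis	3	0.0	0.0	3
wound_bed	epidermis	7	0.0	0.0	3
wound_bed	epidermis	10	0.08	0.004	3
wound_bed	epidermis	15	0.44	0.04	3
wound_bed	dermis	0	0.27	0.07	3
wound_bed	dermis	3	0.02	0.01	3
wound_bed	dermis	7	0.04	0.003	3
wound_bed	dermis	10	0.10	0.004	3
wound_bed	dermis	15	0.16	0.007	3
wound_bed	whole	0	0.29	0.07	3
wound_bed	whole	3	0.02	0.01	3
wound_bed	whole	7	0.045	0.004	3
wound_bed	whole	10	0.098	0.004	3
wound_bed	whole	15	0.169	0.009	3
outer_edge_1	epidermis	0	0.4	0.1	3
outer_edge_1	epidermis	3	0.01	0.01	3
outer_edge_1	epidermis	7	0.04	0.01	3
outer_edge_1	epidermis	10	0.1	0.04	3
outer_edge_1	epidermis	15	0.2	0.02	3
outer_edge_1	dermis	0	0.08	0.02	3
outer_edge_1	dermis	3	0.004	0.001	3
outer_edge_1	dermis	7	0.01	0.001	3
outer_edge_1	dermis	10	0.01	0.002	3
outer_edge_1	dermis	15	0.05	0.003	3
outer_edge_1	whole	0	0.22	0.04	3
outer_edge_1	whole	3	0.01	0.003	3
outer_edge_1	whole	7	0.023	0.005	3
outer_edge_1	whole	10	0.06	0.024	3
outer_edge_1	whole	15	0.12	0.008	3
wound_center	epidermis	0	0.2	0.02	3
wound_center	epidermis	3	0.0	0.0	3
wound_center	epidermis	7	0.0	0.0	3
wound_center	epidermis	10	0.0	0.0	3
wound_center	epidermis	15	0.09	0.02	3
wound_center	dermis	0	0.13	0.02	3
wound_center	dermis	3	0.003	0.001	3
wound_center	dermis	7	0.009	0.003	3
wound_center	dermis	10	0.016	0.001	3
wound_center	dermis	15	0.066	0.01	3
wound_center	whole	0	0.132	0.021	3
wound_center	whole	3	0.003	0.001	3
wound_center	whole	7	0.008	0.003	3
wound_center	whole	10	0.015	0.001	3
wound_center	whole	15	0.07	0.01	3
outer_edge_2	epidermis	0	0.28	0.07	3
outer_edge_2	epidermis	3	0.03	0.004	3
outer_edge_2	epidermis	7	0.06	0.006	3
outer_edge_2	epidermis	10	0.15	0.011	3
outer_edge_2	epidermis	15	0.243	0.018	3
outer_edge_2	dermis	0	0.13	0.01	3
outer_edge_2	dermis	3	0.006	0.002	3
outer_edge_2	dermis	7	0.009	0.004	3
outer_edge_2	dermis	10	0.04	0.01	3
outer_edge_2	dermis	15	0.10	0.003	3
outer_edge_2	whole	0	0.19	0.025	3
outer_edge_2	whole	3	0.01	0.003	3
outer_edge_2	whole	7	0.03	0.005	3
outer_edge_2	whole	10	0.092	0.0085	3
outer_edge_2	whole	15	0.16	0.009	3
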
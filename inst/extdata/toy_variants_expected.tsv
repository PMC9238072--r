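variant_id	pass	reason	impact	max_external_maf
v01	TRUE	NA	high	0.01
v02	FALSE	qual	high	0.01
v03	TRUE	NA	high	0.01
v04	FALSE	missingness	high	0.01
v05	TRUE	NA	high	0.01
v06	FALSE	private_af	high	0.02
v07	FALSE	excess_het	high	0.45
v08	TRUE	NA	high	0.45
v09	TRUE	NA	high	0.01
v10	TRUE	NA	low	0.01
v11	TRUE	NA	low	0.01
v12	TRUE	NA	low	0.01
v13	TRUE	NA	low	0.01
v14	TRUE	NA	none	0.01
v15	TRUE	NA	none	0.01
v16	TRUE	NA	high	0.01
v17	TRUE	NA	low	0.01
v18	TRUE	NA	low	0.01
v19	TRUE	NA	high	0.01
v20	TRUE	NA	low	0.01
v21	TRUE	NA	high	0.15
v22	TRUE	NA	high	0.05
v23	TRUE	NA	high	0
v24	TRUE	NA	high	0.004
v25	TRUE	NA	high	0.004
v26	TRUE	NA	high	0.01
v27	FALSE	missingness	high	0.01
v28	TRUE	NA	low	0.01
v29	TRUE	NA	high	0.3
v30	TRUE	NA	high	0.01
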
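case_id	variant_id	chrom	pos
C01	V01	chr1	150
C02	V02	chr1	150
C03	V03	chr1	150
C04	V04	chr1	150
C05	V05	chr1	5000
C06	V06	chr1	150
C07	V07	chr1	150
C08	V08	chr1	150
C09	V09	chr1	150
C10	V10	chr1	150
C11	V11	chr1	150
C12	V12	chr1	150
C13	V13	chr1	150
C14	V14	chr1	150
C15	V15	chr1	150
C16	V16	chr1	150
C17	V17	chr1	150
C18	V18	chr1	150
C19	V19	chr1	150
C20	V20	chr1	150
C21	V21	chr1	150
C22	V22	chr1	150
C23	V23	chr1	150
C24	V24	chr1	150
C25	V25	chr1	150
C26	V26	chr1	150
C27	V27	chr1	150
C28	V28	chr1	150
C29	V29	chr1	150
C30	V30	chr1	150
C31	V31	chr1	150
C32	V32	chr1	150
C33	V33	chr1	150
C34	V34	chr1	150
C35	V35	chr1	150
C36	V36	chr1	150
C37	V37	chr1	150
C38	V38	chr1	150
C39	V39	chr1	150
C40	V40	chr1	150
C41	V41	chr1	150
C42	V42	chr1	150
C43	V43	chr1	150
C44	V44	chr1	150
C45	V45	chr1	150
C46	V46	chr1	150
C47	V47	chr1	150
C48	V48	chr1	150
C49	V49	chr1	150
C50	V50	chr1	150
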
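case_id	variant_id
C01	V01
C02	V02
C03	V03
C04	V04
C06	V06
C07	V07
C08	V08
C09	V09
C10	V10
C11	V11
C12	V12
C13	V13
C14	V14
C15	V15
C16	V16
C17	V17
C18	V18
C19	V19
C20	V20
C21	V21
C22	V22
C23	V23
C24	V24
C25	V25
C26	V26
C27	V27
C28	V28
C29	V29
C30	V30
C31	V31
C32	V32
C33	V33
C34	V34
C35	V35
C36	V36
C36	V36_splice_extra
C37	V37
C38	V38
C39	V39
C40	V40
C41	V41
C42	V42
C43	V43
C44	V44
C45	V45
C46	V46
C47	V47
C48	V48
C49	V49
C50	V50
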
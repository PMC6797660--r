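gene_id	length_bp	mutation_types	n_stop	n_stop_next_to_Q
Td-α-A1	924	Stop codon	2	1
Td-α-A2	879	Stop codon	2	2
Td-α-A3	785	Stop codon	1	1
Td-α-A4	859	Frameshift and stop codon	1	1
Td-α-A5	859	Frameshift and stop codon	3	2
Td-α-A6	583	Deletion at 5′ end, frameshift, and gap	0	0
Td-α-A7	696	Deletion at 5′ end, frameshift, and stop codon	2	1
Td-α-A8	859	Stop codon	4	2
Td-α-A9	846	Stop codon	2	2
Td-α-A10	834	Stop codon	2	1
Td-α-A11	837	Stop codon	1	1
Td-α-A12	845	Frameshift and stop codon	8	5
Td-α-A13	845	Stop codon	3	1
Td-α-A14	894	Intact full-length		
Td-α-A15	870	Stop codon	1	0
Td-α-A16	456	Deletion at 3′ end and stop codon	2	0
Td-α-A17	887	Intact full-length		
Td-α-A18	845	Frameshift and stop codon	5	1
Td-α-A19	579	Frameshift, stop codon, and gap	1	0
Td-α-A20	861	Intact full-length		
Td-α-A21	858	Intact full-length		
Td-α-A22	859	Deletion at 5′ end		
Td-α-A23	855	Stop codon	1	1
Td-α-A24	849	Stop codon	1	1
Td-α-B1	949	Intact full-length		
Td-α-B2	996	Intact full-length		
Td-α-B3	1023	Stop codon	1	1
Td-α-B4	969	Intact full-length		
Td-α-B5	927	Stop codon	1	1
Td-α-B6	918	Intact full-length		
Td-α-B7	765	TE insertion and stop codon	3	3
Td-α-B8	852	TE insertion and stop codon	3	3
Td-α-B9	813	Deletion at 5′ end and stop codon	3	3
Td-α-B10	1104	TE insertions and stop codon	1	0
Td-α-B11	231	Deletion at 5′ end and stop codon	1	0
Td-α-B12	669	Deletion at 5′ end and stop codon	1	1
Td-α-B13	606	Stop codon	2	0
Td-α-B14	146	Deletions at both 5′ and 3′ ends		
Td-α-B15	885	Intact full-length		
Td-α-B16	237	Deletion at 5′ end and stop codon	1	0
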
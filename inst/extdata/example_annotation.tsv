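taxon_id	phylum	multicellular	replicon_id	gene_id	start	end	strand	protein_id	architecture	sequence
Demobacterium contextus	Unknown	NA	CP000001	AAA00001.1	101	400	+	AAA00001.1		MTFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSML
Demobacterium contextus	Unknown	NA	CP000001	AAA00002.1	501	800	-	AAA00002.1		MLAWTQQRGRMFSTTVCGGGYRCLNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQS
Demobacterium contextus	Unknown	NA	CP000002	AAA00003.1	50	280	+	AAA00003.1		MTMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFV
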
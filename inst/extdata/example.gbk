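LOCUS       CP000001                5000 bp    DNA     circular BCT 01-JAN-2020
DEFINITION  Demobacterium contextus chromosome (synthetic fixture).
ACCESSION   CP000001
SOURCE      Demobacterium contextus
  ORGANISM  Demobacterium contextus
            Bacteria.
FEATURES             Location/Qualifiers
     source          1..5000
                     /organism="Demobacterium contextus"
     CDS             101..400
                     /locus_tag="DEMO_0001"
                     /protein_id="AAA00001.1"
                     /translation="MTFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGG
                     CYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSML"
     CDS             complement(501..800)
                     /locus_tag="DEMO_0002"
                     /protein_id="AAA00002.1"
                     /translation="MLAWTQQRGRMFSTTVCGGGYRCLNKACCMQCCLFLTTFDQQAF
                     DPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQS"
//
LOCUS       CP000002                2000 bp    DNA     circular BCT 01-JAN-2020
DEFINITION  Demobacterium contextus plasmid (synthetic fixture).
ACCESSION   CP000002
SOURCE      Demobacterium contextus
  ORGANISM  Demobacterium contextus
            Bacteria.
FEATURES             Location/Qualifiers
     source          1..2000
     CDS             join(50..150,201..280)
                     /locus_tag="DEMO_0003"
                     /protein_id="AAA00003.1"
                     /translation="MTMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNWLFCDCQSE
                     GYYMAQAEPGNHNFV"
//
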
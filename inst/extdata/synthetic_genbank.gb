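LOCUS       SYN00001                 612 bp    DNA     linear   PLN 15-MAR-2012
DEFINITION  Synthetic symbiont ITS record (constructed fixture, not a real
            database entry).
ACCESSION   SYN00001
SOURCE      Synthsymbiont demo
  ORGANISM  Synthsymbiont demo
            Fungi; Agaricomycetes.
FEATURES             Location/Qualifiers
     source          1..612
                     /organism="Synthsymbiont demo"
                     /host="Macrotermes michaelseni"
                     /country="Kenya: Thika"
ORIGIN
        1 acgtacgtac gtacgt
//
LOCUS       SYN00002                 598 bp    DNA     linear   PLN 02-JUL-2008
DEFINITION  Synthetic symbiont ITS record, genus-level host only.
ACCESSION   SYN00002
SOURCE      Synthsymbiont demo
  ORGANISM  Synthsymbiont demo
FEATURES             Location/Qualifiers
     source          1..598
                     /organism="Synthsymbiont demo"
                     /host="Odontotermes sp."
//
LOCUS       SYN00003                 605 bp    DNA     linear   PLN 20-JAN-2003
DEFINITION  Synthetic symbiont ITS record without host qualifier.
ACCESSION   SYN00003
SOURCE      Synthsymbiont demo
  ORGANISM  Synthsymbiont demo
FEATURES             Location/Qualifiers
     source          1..605
                     /organism="Synthsymbiont demo"
                     /isolation_source="fungus comb nodule"
                     /country="Kenya"
//
LOCUS       SYN00004                 590 bp    DNA     linear   PLN 11-NOV-1999
DEFINITION  Synthetic symbiont ITS record with no source metadata.
ACCESSION   SYN00004
SOURCE      Synthsymbiont demo
  ORGANISM  Synthsymbiont demo
FEATURES             Location/Qualifiers
     source          1..590
                     /organism="Synthsymbiont demo"
//
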
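LOCUS       minicontig               600 bp    DNA     linear   BCT 01-JAN-2026
DEFINITION  Synthetic mini contig used in examples and tests.
ACCESSION   minicontig
FEATURES             Location/Qualifiers
     source          1..600
                     /organism="synthetic construct"
     CDS             101..200
                     /locus_tag="gene_A"
                     /product="site-specific integrase"
     CDS             complement(251..340)
                     /locus_tag="gene_B"
                     /product="AlpA family excisionase"
     CDS             join(361..400,421..460)
                     /locus_tag="gene_C"
                     /product="hypothetical protein"
     tRNA            481..556
                     /locus_tag="trna_Phe"
                     /product="tRNA-Phe"
     CDS             561..590
                     /locus_tag="gene_D"
                     /product="integrase"
                     /pseudo
ORIGIN
        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
       61 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      121 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      181 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      241 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      301 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      361 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      421 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      481 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      541 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
//
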
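LOCUS       SYN_PHAGE01             2400 bp    DNA              UNK 01-JAN-1980
DEFINITION  synthetic phage test record (not a real deposit).
ACCESSION   SYN_PHAGE01
VERSION     SYN_PHAGE01.1
KEYWORDS    .
SOURCE      .
  ORGANISM  .
            .
FEATURES             Location/Qualifiers
     CDS             1..300
                     /product="hypothetical protein"
     CDS             351..950
                     /product="hypothetical protein"
     CDS             1001..1600
                     /product="hypothetical protein"
     CDS             1701..2300
                     /product="hypothetical protein"
     tRNA            2311..2385
                     /product="tRNA-Met"
     source          1..2400
ORIGIN
        1 tttcctcatg caattcaaaa ccatgtccgt aatgtaggcg aaatagtaaa ccattttacg
       61 gaggatacca aattcctcct tattcaggac ctaacctgag nryaaccagg tctctccgcc
      121 cccttataaa agctgttgca cctagccaag ttcaacggca gctgcaatgg aaataggcaa
      181 tgacggatat atattaaaaa gtgttttaag atacattgag gcccgttcgt gctcctcgcc
      241 ctgaagcatt gctttgtgaa gagggacttc agccaataga cctgcatacc ggctcattct
      301 tcatgtgcaa cctagggaga atgtgtacat acgctcttac tgcggtcgcg tctaataata
      361 tacatttgct tcgttgacta gcaacccagg gctatagcta ttccccccgc ggcccaccca
      421 gtattcctaa cggagcataa atcccacccg aactaagttt gtcgaacctt ggtccaagat
      481 cgggactcgg tctccaggta agacgggctc attcataaac gttactaagg ggtataatct
      541 tctatttgtg ggtgggaaca cttagtagac ttgcaatcca attacagcag tcttgtgcgc
      601 ctaggggcgc cccaaaggta aacgaaccgt tgcggtcaat cttgtcgcgg ctgatgaatt
      661 tgaagcagtg gccgggagtg tgtgctcagg agttcgtccc atgacacgat agagagagaa
      721 catcctgttg ggcttaatga tatagaattc cctcgcttgg atgagccata tagaccgcct
      781 ctcgtcgtgt tgatctacct gacatgtctc tcgcgcgacc acccaggatt agactcatca
      841 ttcgggtagt agacattata ttcgataccg tggtagccta gggtgttaac acccctataa
      901 cacattagtc ccttgtatgc aggcggtatc ggacggcgcc cacaccttgg aggtatccag
      961 cgcaaggcgc catatccgta ccttactatc gcgcgaactt atgttgtttt aagttagagt
     1021 tggacatcta tacgtcagtc ctaaacatag cgagcatttc gcagatgggt ctccgacggt
     1081 accccaaggg tcgttaccga cgccgggacg ccgcatataa aggtacgccc gaccattata
     1141 caggtagcca tctgcgtctg acatcgcatt tgaaacccag taggtactgc cttagttgca
     1201 ctcctaactc atgttaacgg acttacgggc actagcttct tactgccctc tctgtttctc
     1261 ttaagggacg tcgagacgcc aagttatgga gtctacccac gtttcggttc cgttctgcag
     1321 ggccaataga cgagcgatat tattggtgcc tctcgcagtc tggatagatg attgtggaaa
     1381 gggggcttgg acaattagat tttacggtgt accgcgccat actagggaag ctccccgtgg
     1441 tggtccggcc aaagattact taggttgggg cgcctcgccc tgccatcggt gttcacaacg
     1501 gatgatcgag tgcttctcgc tcagttacga gcgtggcatc ggacaagaac gtccttatgt
     1561 acggcgctac acaaggagat acagagcttg atttgaaccg tgggtgggag aggcccacgc
     1621 cgaccggcta atatagcacg aagttcttcg atgcgactac gttaattttt ctaattgaag
     1681 ctgggcttac tacccaagga cagggtcatc tgcaattcat aacgcagagc gatctattaa
     1741 cgcttagggc cccctacgag gggcaacggt ccagtgtgtc aagtctagag atcttctcta
     1801 gtggtggaca tgcgttggaa atcagagaga ctagctgtac attcaaattc ctgctaaacg
     1861 tattcaggaa gtaagaacca gggccttact catcacccta taccatcgat atgattgacg
     1921 atgtccatgg gcgatttgtg taagactgtc agaggtctag taagcgggca gctagaacgg
     1981 tgtagaatcg gagccggata tacgacattg acatctttat gaagaatgac atgcacgtta
     2041 ttctttttac gcagcgtttt gcttgatcgg tagagtccta cttttaccag cagctgtctg
     2101 gaccccgacc cgggaggacg acggggcgta gaggctccac ggatgcttgg cggcaaagaa
     2161 acgggcaaca tcatcagtca tctcataacg ggcgcctatg cacaaaggat accaagactc
     2221 tggcgtacga gggtctcccc gttcgccgga cgcaggcaca actcatcgga atctcgctga
     2281 taatatatcc acctcggccc gacccctgga gcacgaaggc agtgaacaag ccgagttgtt
     2341 acctattagc actcaactta tacgacgagg gtggcgcttt ggtcctgcgc tcggaagtat
//
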
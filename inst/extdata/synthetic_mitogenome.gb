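LOCUS       SYN0001 16768 bp    DNA     circular VRT 01-JAN-2026
DEFINITION  Synthetic mitochondrion, complete genome (fixture).
FEATURES             Location/Qualifiers
     source          1..16768
                     /organism="Synthetica exempli"
     tRNA            1..70
                     /product="tRNA-Phe"
     rRNA            73..1002
                     /product="12S ribosomal RNA"
     tRNA            1005..1074
                     /product="tRNA-Val"
     rRNA            1077..2676
                     /product="16S ribosomal RNA"
     tRNA            2679..2748
                     /product="tRNA-Leu"
                     /anticodon="(pos:2709..2711,aa:Leu,seq:uaa)"
     gene            2751..3707
                     /gene="NAD1"
     CDS             2751..3707
                     /gene="NAD1"
     tRNA            3710..3779
                     /product="tRNA-Ile"
     tRNA            complement(3782..3851)
                     /product="tRNA-Gln"
     tRNA            3854..3923
                     /product="tRNA-Met"
     gene            3926..4960
                     /gene="NAD2"
     CDS             3926..4960
                     /gene="NAD2"
     tRNA            4963..5032
                     /product="tRNA-Trp"
     tRNA            complement(5035..5104)
                     /product="tRNA-Ala"
     tRNA            complement(5107..5176)
                     /product="tRNA-Asn"
     rep_origin      5179..5213
                     /note="origin of L-strand replication"
     tRNA            complement(5216..5285)
                     /product="tRNA-Cys"
     tRNA            complement(5288..5357)
                     /product="tRNA-Tyr"
     gene            5360..6910
                     /gene="COX1"
     CDS             5360..6910
                     /gene="COX1"
     tRNA            complement(6913..6982)
                     /product="tRNA-Ser"
                     /anticodon="(pos:6943..6945,aa:Ser,seq:uga)"
     tRNA            6985..7054
                     /product="tRNA-Asp"
     gene            7057..7740
                     /gene="COX2"
     CDS             7057..7740
                     /gene="COX2"
     tRNA            7743..7812
                     /product="tRNA-Lys"
     gene            7815..7979
                     /gene="ATP8"
     CDS             7815..7979
                     /gene="ATP8"
     gene            7982..8665
                     /gene="ATP6"
     CDS             7982..8665
                     /gene="ATP6"
     gene            8668..9451
                     /gene="COX3"
     CDS             8668..9451
                     /gene="COX3"
     tRNA            9454..9523
                     /product="tRNA-Gly"
     gene            9526..9874
                     /gene="NAD3"
     CDS             9526..9874
                     /gene="NAD3"
     tRNA            9877..9946
                     /product="tRNA-Arg"
     gene            9949..10245
                     /gene="NAD4L"
     CDS             9949..10245
                     /gene="NAD4L"
     gene            10248..11625
                     /gene="NAD4"
     CDS             10248..11625
                     /gene="NAD4"
     tRNA            11628..11697
                     /product="tRNA-His"
     tRNA            11700..11769
                     /product="tRNA-Ser"
                     /anticodon="(pos:11730..11732,aa:Ser,seq:gcu)"
     tRNA            11772..11841
                     /product="tRNA-Leu"
                     /anticodon="(pos:11802..11804,aa:Leu,seq:uag)"
     gene            11844..13664
                     /gene="NAD5"
     CDS             11844..13664
                     /gene="NAD5"
     gene            complement(13667..14185)
                     /gene="NAD6"
     CDS             complement(13667..14185)
                     /gene="NAD6"
     tRNA            complement(14188..14257)
                     /product="tRNA-Glu"
     gene            14260..15399
                     /gene="COB"
     CDS             14260..15399
                     /gene="COB"
     tRNA            15402..15471
                     /product="tRNA-Thr"
     tRNA            complement(15474..15543)
                     /product="tRNA-Pro"
     D-loop          15546..16745
                     /note="control region"
ORIGIN
//
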
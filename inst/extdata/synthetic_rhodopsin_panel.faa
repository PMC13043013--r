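>SYNRHO1|rhodopsin subtree=I synthetic proteorhodopsin anchor (Bacteroidota-type)
GIAWPSATRTGGREQGPFQPSPKIGDIRHRTPVAKGNTLITRKRGIAYFGPKEDAGSLTEFTAMMIACEELHKANRKGFGKEDRDFPITVGFRDKEPDTDLECPGIAGYLNLEMQKLFTFVIEKVLSLKCLAERSPDGEAQELSVDTGIVVRQQKGESGIMEIQIIEPEESEAKFNQETFVGCSDEAKGGSGGFCIQGKLGLRKGTDRISMNCEDNMYKLPYAFDCMQKTHKEFVDKFGHMLLKYIVAFIAMLKISPVTDNNYLFGPQKGAAWVAVNQSGRFGTLNNEMSNKRILCQAAR
>SYNRHO2|rhodopsin subtree=II synthetic proteorhodopsin anchor (E. sibiricum-type branch)
GAKWPSDQRTGGREQGPFQPHWYIGDIRFRMPVAKGNTLISRKRGIAYFGMKEDAGSLTEQTAPMIWCTYTHDANRKGFGKEDRDFPLTVGFRDFEPDTDLACPFIAYMLYTEMHYLRTFVMEKVLSLKCLAERLQDQEAQELVVDTAMVVRQQVGESDIMEIQSIEPEESEAKFEQEHFVGSTDSANGGNGGICFGRKLGLRNGTPRLSMLCHENMYKLPYAFDCMQGTHKHLIDKYSHMLLKYFVAFIATLDVSPVPDNNRLFGPQHPMAWWAVNNSGRFGTLNNEMSGKRILKVAMD
>SYNRHO3|rhodopsin subtree=III synthetic xanthorhodopsin anchor
QIAWPSKHRQGSPEWLPFPPDPKFGDIRHRTPFAKGLTRITLKRGNAYFGPKFDAGWLTEFPAMKIACEELHDKNRKGFAIEDRDFAITVGHWRHEKDQDLECPAPETYLLLCMRKLFGFVGMKVYCLKCLAPRNEDGEAQIASVDTDIVPRQQTGESGIMEIQHIIPEESEAKFNQETPVGLSDEAEGGSGGFCIIYKSFMRLGTDPIKPHCEDNMKRLPYAFDHLQPMHKEFVDKFGHMPLKYIVAFIAMLKILCVVWNNYLWMPQTGAAWHAVNQSGRFGTLNNKMSNKIWLCFAAR
>SYNBLH1|brp_blh synthetic beta-carotene 15,15'-dioxygenase
RWCLLAFGPFEGDYFEDVQRTLIAIIDSSSKSKRPAALSSFDHSDVQVESTIEALKGMDYKLLDVLNAGIIPFSSRNDVAISRKLTGEETRQALGQYHEGSGIKEQSIPNLKEQVFAGLLFNRLSARSRFIIVAGEAAHAFQREAFDREELVQLEVEAHSDKISSYTKAEGTNELIPNIQLAYEFVSLEYDRVPVWHTTKGVVGLKLEEIHAQLLEFSCDQVLLEDFVAKECCLKAEIAILERDVNGPRDKCSNILGLGS
>SYNCRTY1|crtY synthetic lycopene cyclase
GAGPTVGARGFFLRYLGTQFHIAPARGLWFMQPVEGARSGWVQQGEEDLVKNIAKYSVLMGKKLLHMVPQEKVKQDRGPIVNSEILLGFGILLLGGPMMPAPLFRFTSNISDDMAIYADCDSTSNPSNTSFQYNAVSRFEDKIESFIFVVEGESLARKSDILPATNKMAGLTRVRDFRCTSLYTSVGKQKQGDTVANEMALEQAFLLPNAVNDTVGGNDRQELGALGNRIVELTFFTRDL
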
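>MT_seed_01
RLQSNADTRGCETNFNPLVTRGYSIIFFLNDNFKKNSLDQLFNGFGQQHQSHAVYNQAIINADCKQEEISINIRGNHHRN
MQISEEKGTNLMSKCQKPSYDLMRGNQDRLELMKMLPQDPGRDMWMEAKRHAAKHNNNWLLTVYARFLDDDADQFDPHIF
LQTNLGHASPKHPVFSHQLFYEPCILLDAEKKEMNLREYWVTQLFAMLLTWYGLLDLDLVADKLIGKIIIDSFLKPPVGG
LQVADDIDENFRQNNDFLNSNGSALCEYLVPPVCRTDGPLQGQYSPTRQTTSAGKKKHQT
>MT_seed_02
RLQSNADTRPCLTNFNPLVTRGYSLIFNLNDNFKKNSLYFLFNGFGMFEQSHANVNQAIIGADRKQEEISIKIRQNGHRN
MQISEEKGTNLMSKCQKPSFDLERGIRDRIELMKSLMQDPGRDMWMEAKRHAAYHNNAWLLTVYANFLDYPADQFDPHFF
LQTNLGHASPKHPVFSHYLFYEPCVLLDAEKKEMNLQEYWVTQLFAMGLTWYGLLDLDAVADKLIGKIIIDSFLKPPVGG
LQVADDIDENFRQNNNQLNYNGSALCEYLDPPVCRTDGPLQGQPSPTRQTTSAGKKKHGT
>MT_seed_03
RLQSVADKRGCETNFNPLVTRGYSIIFFLPDNFKKNSLDQLFNGVGQTHQSHQVYNQAIMNADSLQEEISINIRGNHHRN
MQLSEEKGTNLMSKCQKPSYDLMRGNQNRLELMKMLPQDPGRDMQMEAKRHAFKHNNNWLLTNYARFLDVDADQFDPHIF
LRTNLGVASPKHPVFSHQQFYSPCILLDAEKPEMNLREYWVTQEFFMLLTWYGLLDLFLPADKLIGKIIIDSFLKTPPGG
LQVADAIDTNQRQNNDFLNSNGGALCEPLVPPVCRTDGCLQGQYSPTRQTQSAGKKKHQT
>MT_seed_04
RLQSNADTRGCETNFNPLVTAGYSVIFGGFRNFKKNSLDQLYNGFGQQHQVHAVYNQAIINADCKQEEASINIPGNHHRN
MQISEEKGTNLMSKCQKPSYDLMRGNQDRLELMKMLPYDPGRDMWMEAKDHAAKVNNNTLLTVYARFLDDDKDQFDPHIF
LQTNLGHASPKHPAFSHQLFYEPCDLLDAEKKEMNLRDYWVTQLFVMLLTWYHLLLLDLVADKLQGGIRIRSFLKPPVPL
LQVTYLIDENFRQNNDFLNSNGSALDEYLVPPVCRTDGPLQGQYSPTAQTTSAPKKKHQT
>MT_seed_05
RLQSNADTRGCETNFMPLKTTGASIIFFTNDNFKKNGLDQLRNGFGQQHQSHAVYNQAIISADCKQEEISINIRGAHHRN
LQISEEKGTNLMSKCQDPSYDLMRGYQDRLELMKMLPQDPDRDMIAEAKRHAAKHNNNWLLTVCIRFLDDCADQFDPHIT
LQTNLGHASPKHPVASHFLFYEPCILLDKEKKEMNLREYWSTQLFTMLLTWYGLLDLDLVADKLIGKITIDSFLKPPVGG
LQVADDFDEKFRQNNDFLPSNGSALCVYLVPPVCVTDGPLQGQYSPTRQTTSTGKKKHQT
>MT_seed_06
RLQGNADTRPCETVFNHLVTRKYSLIFFLIDNFKKNSLDQFFNSFGQEHQSHAVPNQAIINADCKQQEISINIRGDHHRN
MQISEEKGTNLASKCQKKSYLLMRGNQDRLELMKMLPQDPGRDMWMENKRHADKHNKNWLRTVYARFLDDDADQFDPHIF
LQTKPGHASPKHPVNSHQLFYEPCILLDAEKKEMNLREVWVTQLFAMLLTWYSLLDLDLVADKLIGSIIIDSFLKPPVGG
LQVADDIDEMFRQNKDFLNSNPSAVKSYLVPPVCPTDGPLQGQYSKTSQTTHAGKKKHQT
>MT_seed_07
RPQSNADVRGCETNFNPLVTRGYSIIFFLNDSFKKISEDQLENGFGQQHQSHAVYNQAIINADCKQEEISINIRGNHHRN
MQISEEKGTNLMQKCQAPSSDEMRGNQDRMLLMKMLPQLPGRDACMEAKRHAAKHNNNWLLTVYVRFLDDDADQFDPHIF
LLTNLGHASPKHPVFSHQLFYELAILLDAEKKEVNSPEYWVTQLFAMLLTWYGLLDLDLVEDYLIGKIIIDSFLKPPVGG
LQVARDWDENFRQNNDILNSNGSALCENLVPPVCRTDGPLQGQYSPTRQTTSALKKKHGT
>MT_seed_08
RLQSNADTRGCETNFNPLVTRLYSIIFFLNDNFKKNFLDYLFNDFGQQGQSHAVYNQAIINRDCKQEEILINIRGNHHRN
MQISEEKGDNLMSKCQKPSYDLMRGNGDRLILMKMGYQDPGQDMWMEAMRHAAKHNNNWLSTVYARFLDDDADQFDPHIF
LQTNLGHASPKVPVFSHQLFYEPCILLDAEKKEMNLREYLVTQLTAMLLTWYGLLDLDLGADKLIGKIIIDSFLKPLVGG
VQVGDIIDENFRSNNDFLNSNGSALCEYLVPPVCRTDGPLQGVYSPTRQTTSAGKKKHQT
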
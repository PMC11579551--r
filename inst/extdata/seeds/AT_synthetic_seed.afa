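>AT_seed_01
PFAGMTSVVANDGWNTLAMDNLEKENVRAEKGWAAGDAEFREMEQKCLLFELFPQTIAANTEFNESFKAMVESATVTKVR
TGVRYDQAGGASLKCGGLADDMAKKHADQLNNSVPFFEILVNIAKPIAEIIQAECVEAFNYSGQTETHTQ
>AT_seed_02
PFAGMTSVVANDGENTLGMDNLEKANVRAEKGWAAGDAEFREMEQKCLLFELDPQTIAANTEFNESPKAMVESATVTKVR
TGERYDQAGGASLSCGGLFDDWAKKHADQLNNSVPFFEIFVNTAKPIAEIIQAECVEAVNYKGQTETHTQ
>AT_seed_03
MFAGMTSVVANDAWNTQAMDNLEKENLRAEKCWAAGDLEFREMEQECLLFELFPQTIAANTEFNESKKAMVASATVTKVR
TGVRYDQAGGAILKCGGLADDMAKKHADQLNNSVPFFEILVNIKKPIAEIIQYECVEAFNYSGQTETHTQ
>AT_seed_04
PFAEMTSVGANDGENTLAMDNLEKEDVQAEKGWAAGGAEFRGMEQKCLLFELFPQTSAANTEFNISFKAMVESAFVTKVR
TGVRYVQAGGASLKCGGLAKRMAKKHADQLNNSVSFNEILVNIGKPIAEIIQAECVEANNYFGFTETHTQ
>AT_seed_05
PFVGRTSVVANDPWNTLEMDNLEKENVRAEKGWAAGDAEFREMEQKCLLFELFPQTIAANTEFNESFKAMVESATVTKVR
TGVRYDQAGGASLKCGDLADDMAKKHADQLNNSVPFFEILVNIAKPIAIIIQAEKVEAPNYRGQTYTHTQ
>AT_seed_06
PFAGMTSVVANAGVNTLAMLNREKENVRAEKGWAAGDAEFREMEQKCTLFELFPQTIAANTPFNESFKSMVESATRTSVR
TGVRYDQAGGASLKRGGLADDMAKKHADELNNSVPFFEILVNIAMPISEIIQAECVEAFNFSGMTQTHTQ
>AT_seed_07
AFAGMTSVVANDGNNTLAMDNLESENVRGEKMWDAGDACLRMMEGKCLIFELFPQTIAANTEFNESFKAMVESATVTLVR
TGVRYDQAEYLSLKSGGLADDMAKKNAKQLNTSVPFFEILVTIAKTIAEIIQAECKEAFNESGQTTTHTQ
>AT_seed_08
PFAGMTSVVANDGWITLSMDNLCKENVRAEKGWAAGDAEFREMEQKCLLFELFPQTIAANTEFNESFKAMVESATVLKVR
TGVRYDQAGVASLKKGGLADDMAKKHADQRNNSVPFFSILVNIAKKIAEIIQAECVEAFDYSGQTETHTQ
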
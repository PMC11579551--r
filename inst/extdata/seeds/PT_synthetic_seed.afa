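>PT_seed_01
VSQINSVPFYRLGGFYVGYGLSTIALTTTIYTFAESMIRSKEKKQLLQKGHRYLEGLLHASIYVRTKRQWAFLAPKWKYL
LASDTEQDKMNHIETSKTGPNADRVLDTDLFVNVKVLLMFLMASVHSNSVVEYQYKDMGL
>PT_seed_02
VEQANSVPFYRLGGIYVGYGLFTIALTTTIYTFAESMIRSKEKKQLLQKGHRYLEGLLHASIYVSTKRQWAFLAPKWKYL
LASDTEQDKMNHIETSYAGPNPDRVLRTDLSVKVKVLLMFLMASVHSNSVVEYQYKDMGL
>PT_seed_03
VSQINSLPFYRLGGFYAGYGLSTIALTTTRYTFYESFIRSKEKKFLLQKGHTQLEGLLHASIYVRTKRQWAFLAPKWKYL
LASLTEFDKMNPIETSKTGPNVDRVLDPDLFNNVKVLLMFLMPSVNSNSVVEYQYKDTGL
>PT_seed_04
VSQINSVPFYALGGFYVGYGLSYIALTTTIYTFAESMIRSKEKKQLLQKGNRYLETLLHASIYVDTKRQWAFLAWVWKYL
LASDTEQDKMNHIEPSKTGPNADHVLDTDDFVNKKVLAMFLMASVHSNSVVEYQYKPMGG
>PT_seed_05
VSQSNSSPFYRLGGFYVGSGLSTIALTTTIYTFAESMIRYKEVKQSLQKGHRYLEGLLHASIYVRTKRQWAFLAPKWKYL
LASDQEQDKMNHIETSEDGPNADRLLDTDIFVNVKVLLMFLMASVHDNSVPLYTYPDMGL
>PT_seed_06
VSQINSVPRYRLGIFYVGYGLSTIFLTTTIYTFAESMIRSKEKWQLLQSGHRYLEGLLHNSIYVRTKRQWAFLAPKWKYL
LASDTEQDKMNHIETSKTGPNADRVLDTDLFVNVKVLLEFLMSSVHSNSVVEYQYKDMGL
>PT_seed_07
VSQINSVPFYRLGGFYVGYGLSTILLTTTIYTFAESMIRSKEKKQTLQKLNRATEGLLHASIYVRTKRQWAKLGPKWKYL
LASDTEQDKMNHIETSKTGPNADRVLDTDLFVNVKVLLDFLMASVHSPSVNEYQYKDLGL
>PT_seed_08
VSQINSVPFYRLGGFPVGYSLSTIAATTVIYTFAESMIRSSEKKQLLQKGHRILEGLLSASKYVRTKRQTNFLAQKWKVL
WASDTEQDKMNHIEFSKTGPNADRVLDTDLAVNVKVLLMFLMAPVHSNSVVEYQYKDMGL
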
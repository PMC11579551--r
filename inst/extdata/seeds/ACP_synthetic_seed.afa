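>ACP_seed_01
FGGSFDSEHHDYNLLFPSTAVHLTGLGEILKRLPILTQGVLMNQSPEQGVGVSGTDCMTNVSSTGVDPRE
>ACP_seed_02
FGGSFDSEHHDCNLLFPSTAVHLTGQGEILKRLPILTQGVNMNQSPEKGVGVSGTDCMTNVSSTGVDPRE
>ACP_seed_03
FGGSFDSEHHDYNPSFPSTAVHLTGLGEILKRLPILTQGVLMNQSPEQAVGVSGTDCMTNVSSTGVDPTR
>ACP_seed_04
FGGSFDSEHHDYNLLFPSTAVHLTGSGERLKRDYILTQGVLMNQSPEGGVGVSAFDCMTNVSITRVDPDE
>ACP_seed_05
FGGSFDEEHHDYTLLFPVTAVHRTGLGVILKRLPILTQGVLMNQSPEQGVGVSGTDCWLNVSSTGVDPRE
>ACP_seed_06
FGGSFLSEHHDYGLLFPSTAVHLTGLGEILKRLPILTQGVLMNQSPEQGVGVSGTDCMTNNSLTGADPRS
>ACP_seed_07
FGSSPDSEHHDYNLLFPSTSVHLLGLGEILKRLPILTQGVLMNQSPEQGVGHSGTDCMTNVFSTGVDSRE
>ACP_seed_08
FLGSFDSEHHDYSLLTPSTAVHLTGLGEILKRLPILTQGFLMNQSPEQGVGVQGTDCMTNVSSTGVDRRE
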
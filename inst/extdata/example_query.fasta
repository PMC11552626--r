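>demo1 synthetic query with two known phosphosites encoded inline
MKVL@AERPLTGA&KVSDESSARPLSG
>demo2 synthetic query without known sites
GASTRRPLSEKVTLLSAAKDSTV
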
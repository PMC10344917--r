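file,md5
table_smarca2.csv,0d4c334cf325153ed256e997123d8f44
table_brd4_bd1.csv,726b848ae22e11bd73406230a4533693
table_brd4_bd2.csv,fd92418bdfc26443e055df9d9db478bb
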
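>PF00106_1
KITIITGGTRGIGFAAAKLFIENGAKVSIFGETQEEVDTALAQLKELYPEEEVLGFAPDLTSRDAVMAAVGTVAQKYGRLDVMINNAGITMNSVFSRVSEEDFKNIMDINVNGVFNGAWSAYQCMKDAKQGVIINTASVTGIYGSLSGIGYPTSKAGVIGLTHGLGREIIRKNIRVVGVAPGVVDTDMTKGLPPEIL
>PF00106_2
EVALVTGATSGIGLEIARRLGKEGLRVFVCARGEEGLRTTLKELREAGVEADGRTCDVRSVPEIEALVAAVVERYGPVDVLVNNAGRPGGGATAELADELWLDVVETNLTGVFRVTKQVLKAGGMLERGTGRIVNIASTGGKQGVVHAAPYSASKHGVVGFTKALGLELARTGITVNAVCPGFVETPMAASVREHYS
>PF00106_3
RVALVTGATSGIGLATARLLAAQGHLVFLGARTESDVIATVKALRNDGLEAEGQVLDVRDGASVTAFVQAAVDRYGRIDVLVNNAGRSGGGVTADLTDELWDDVIDTNLNSVFRMTRAVLTTGGMRTRERGRIINVASTAGKQGVVLGAPYSASKHGVVGFTKALGNELAPTGITVNAVCPGYVETPMAQRVRQGYA
>PF00106_4
PVALVTGATSGIGLAIARRLAALGARTFLCARDEERLAQTVKELRGEGFDVDGTVCDVADPAQIRAYVAAAVQRYGTVDILVNNAGRSGGGATAEIADELWLDVITTNLTSVFLMTKEVLNAGGMLAKKRGRIINIASTGGKQGVVHAVPYSASKHGVVGLTKALGLELARTGITVNAVCPGFVETPMAERVREHYA
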
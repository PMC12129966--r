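synonym,canonical
insulin,Regular insulin
insulin regular,Regular insulin
human insulin,Regular insulin
noradrenaline,Norepinephrine
adrenaline,Epinephrine
metamizole,Dipyrone
vitamin k,Phytomenadione
vitamin k1,Phytomenadione
smx-tmp,Sulfamethoxazole + Trimethoprim
sulfamethoxazole+trimethoprim,Sulfamethoxazole + Trimethoprim
co-trimoxazole,Sulfamethoxazole + Trimethoprim
ampicillin+sulbactam,Ampicillin + Sulbactam
ampicillin/sulbactam,Ampicillin + Sulbactam
rifampicin+isoniazid+pyrazinamide+ethambutol,RIPE
unfractionated heparin,Heparin
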
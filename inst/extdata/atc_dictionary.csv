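drug_name,atc_code,atc_class
Regular insulin,A10AB01,Antidiabetics (insulin and rapid-acting analogs)
Morphine,N02AA01,Analgesics (opioids)
Enoxaparin,B01AB05,Antithrombotic agent (heparin group)
Heparin,B01AB01,Antithrombotic agent (heparin group)
Fentanyl,N01AH01,Opioid anesthetic
Amikacin,J01GB06,Antimicrobial for systemic use (Other Aminoglycosides)
Amiodarone,C01BD01,Class III antiarrhythmics
Bromopride,A03FA04,Drugs for gastrointestinal disorders (Prokinetics)
Furosemide,C03CA01,Diuretics (loop diuretics)
RIPE,J04AM06,Antimycobacterial (combination of drugs to treat tuberculosis)
Risperidone,N05AX08,Antipsychotics (other antipsychotics)
Tramadol,N02AX02,Analgesic (other opioids)
Ampicillin + Sulbactam,J01CR01,Antimicrobial for systemic use (Penicillins with betalactamase inhibitor)
Amphotericin B,J02AA01,Systemic antimycotics (Antibiotics)
Carvedilol,C07AG02,Beta-blocking agent
Clopidogrel,B01AC04,Platelet aggregation inhibitors (except heparin)
Scopolamine,A04AD01,Antiemetics and antinauseants
Spironolactone,C03DA01,Diuretics (aldosterone antagonist)
Hydralazine,C02DB01,Antihypertensives (Smooth muscle agents)
Hydrochlorothiazide,C03AA03,Diuretics (Thiazides)
Lactulose,A06AD11,Osmotic laxatives
Levomepromazine,N05AA02,Antipsychotics
Metoclopramide,A03FA01,Drugs for gastrointestinal disorders (Prokinetics)
Neostigmine,N07AA01,Parasympathomimetic (anticholinesterase)
Sulfamethoxazole + Trimethoprim,J01EE01,Systemic antimicrobials (Sulfonamides and Trimethoprim)
Warfarin,B01AA03,Antithrombotic agent (vitamin K antagonist)
Ondansetron,A04AA01,Antiemetics and antinauseants (serotonin antagonists)
Phytomenadione,B02BA01,Vitamin K
Flumazenil,V03AB25,Antidotes
Naloxone,V03AB15,Antidotes
Protamine,V03AB14,Antidotes
Dexchlorpheniramine,R06AB02,Antihistamines for systemic use
Hydroxyzine,N05BB01,Anxiolytics (diphenylmethane derivatives)
Diphenhydramine,R06AA02,Antihistamines for systemic use
Loratadine,R06AX13,Antihistamines for systemic use
Hydrocortisone,H02AB09,Corticosteroids for systemic use
Methylprednisolone,H02AB04,Corticosteroids for systemic use
Promethazine,R06AD02,Antihistamines for systemic use (phenothiazine derivatives)
Prednisone,H02AB07,Corticosteroids for systemic use
Midazolam,N05CD08,Hypnotics and sedatives (benzodiazepines)
Norepinephrine,C01CA03,Cardiac stimulants (adrenergic and dopaminergic agents)
Epinephrine,C01CA24,Cardiac stimulants (adrenergic and dopaminergic agents)
Dopamine,C01CA04,Cardiac stimulants (adrenergic and dopaminergic agents)
Omeprazole,A02BC01,Proton pump inhibitors
Dipyrone,N02BB02,Analgesics and antipyretics (pyrazolones)
Ceftriaxone,J01DD04,Antimicrobial for systemic use (third-generation cephalosporins)
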
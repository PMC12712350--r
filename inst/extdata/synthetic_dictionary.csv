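pt,hlgt,soc
anxiety,anxiety disorders and symptoms,psychiatric disorders
panic attack,anxiety disorders and symptoms,psychiatric disorders
insomnia,sleep disorders and disturbances,psychiatric disorders
sleep disorder,sleep disorders and disturbances,psychiatric disorders
delirium,deliria (including confusion),psychiatric disorders
hallucination,disturbances in thinking and perception,psychiatric disorders
suicidal ideation,suicidal and self-injurious behaviours,psychiatric disorders
completed suicide,suicidal and self-injurious behaviours,psychiatric disorders
depressed mood,depressed mood disorders and disturbances,psychiatric disorders
vision blurred,vision disorders,eye disorders
visual impairment,vision disorders,eye disorders
eye pain,eye disorders nec,eye disorders
dry eye,eye disorders nec,eye disorders
photophobia,ocular sensory symptoms,eye disorders
iris transillumination defect,"anterior eye structural change, deposit and degeneration",eye disorders
pigment dispersion syndrome,"anterior eye structural change, deposit and degeneration",eye disorders
mydriasis,pupil disorders,eye disorders
nausea,gastrointestinal signs and symptoms,gastrointestinal disorders
diarrhoea,gastrointestinal signs and symptoms,gastrointestinal disorders
tendonitis,"tendon, ligament and cartilage disorders",musculoskeletal and connective tissue disorders
arthralgia,joint disorders,musculoskeletal and connective tissue disorders
drug ineffective,therapeutic and nontherapeutic responses,general disorders and administration site conditions
fatigue,general system disorders nec,general disorders and administration site conditions
cardiac arrest,cardiac arrhythmias,cardiac disorders
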
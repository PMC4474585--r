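chest pain	sosy
shortness of breath	sosy
dyspnea	sosy
orthopnea	sosy
fatigue	sosy
palpitations	sosy
peripheral edema	sosy
left atrial dilation	fndg
jugular venous distension	fndg
leg swelling	sosy
hypertension	dsyn
hypercholesterolemia	dsyn
hyperlipidemia	dsyn
diabetes mellitus	dsyn
obesity	dsyn
atrial fibrillation	patf
tobacco use	fndg
coronary artery disease	dsyn
myocardial infarction	dsyn
ischemic cardiomyopathy	dsyn
aortic stenosis	dsyn
mitral regurgitation	patf
valvular heart disease	dsyn
renal insufficiency	dsyn
chronic kidney disease	dsyn
elevated creatinine	fndg
proteinuria	fndg
dysuria	sosy
anemia	dsyn
hematuria	fndg
microalbuminuria	fndg
renal function	fndg
congestive heart failure	dsyn
kidney failure	dsyn
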
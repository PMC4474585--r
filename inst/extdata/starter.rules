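# Starter token-pattern rule pack.
# One rule per line: LABEL => [spec], [spec], ...
# This is a small worked-example grammar around the documented
# noun-phrase + optional copula + participle/adjective pattern, plus a
# few gazetteer-style token rules; it is not a full production rule set.

# compound noun(s) + optional "be" + past participle or adjective,
# filtering normal-condition wordings
SignSymptom => [syn=NN|NNP]{1,3}, [sem=beverb]?, [syn=VBN|JJ, token!="normal"|"regular"|"stable"]

# frequent multiword signs/symptoms
SignSymptom => [token="shortness"], [token="of"], [token="breath"]
SignSymptom => [token="chest"], [token="pain"]

# classic risk factors (single-token gazetteer style)
RiskFactor => [token="hypertension"|"hyperlipidemia"|"hypercholesterolemia"|"obesity"]
RiskFactor => [token="diabetes"], [token="mellitus"]?

# etiologies of heart failure
Cause => [token="coronary"], [token="artery"], [token="disease"]
Cause => [token="myocardial"], [token="infarction"]
Cause => [syn=JJ, token="ischemic"|"aortic"|"mitral"|"valvular"], [syn=NN]{1,2}

# kidney-function-related findings
NonTraditionalRiskFactor => [token="proteinuria"|"dysuria"|"hematuria"|"microalbuminuria"|"anemia"]
NonTraditionalRiskFactor => [token="renal"], [token="insufficiency"]
NonTraditionalRiskFactor => [token="chronic"], [token="kidney"], [token="disease"]
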
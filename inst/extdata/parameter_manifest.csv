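block,key,printed
activity_transition.eurofit,inactive->inactive,0.18
activity_transition.eurofit,inactive->moderate,0.054
activity_transition.eurofit,inactive->recommended,0.71
activity_transition.eurofit,moderate->inactive,0.085
activity_transition.eurofit,moderate->moderate,0.042
activity_transition.eurofit,moderate->recommended,0.82
activity_transition.eurofit,recommended->inactive,0.042
activity_transition.eurofit,recommended->moderate,0.023
activity_transition.eurofit,recommended->recommended,0.89
activity_transition.control,inactive->inactive,0.33
activity_transition.control,inactive->moderate,0.12
activity_transition.control,inactive->recommended,0.49
activity_transition.control,moderate->inactive,0.19
activity_transition.control,moderate->moderate,0.17
activity_transition.control,moderate->recommended,0.58
activity_transition.control,recommended->inactive,0.10
activity_transition.control,recommended->moderate,0.064
activity_transition.control,recommended->recommended,0.80
disease_incidence,inactive->colorectal_cancer,0.015
disease_incidence,inactive->chd,0.011
disease_incidence,inactive->t2d,0.005
disease_incidence,inactive->stroke,0.0046
disease_incidence,inactive->depression,0.010
disease_incidence,moderate->colorectal_cancer,0.011
disease_incidence,moderate->chd,0.009
disease_incidence,moderate->t2d,0.0038
disease_incidence,moderate->stroke,0.0033
disease_incidence,moderate->depression,0.0094
disease_incidence,recommended->colorectal_cancer,0.0096
disease_incidence,recommended->chd,0.008
disease_incidence,recommended->t2d,0.0033
disease_incidence,recommended->stroke,0.0029
disease_incidence,recommended->depression,0.0092
activity_mortality,inactive,0.016
activity_mortality,moderate,0.012
activity_mortality,recommended,0.010
disease_mortality,colorectal_cancer,0.092
disease_mortality,chd,0.002
disease_mortality,t2d,0.015
disease_mortality,stroke,0.400
disease_mortality,depression,0.030
utility.trial,inactive,0.909
utility.trial,moderate,0.919
utility.trial,recommended,0.922
utility.literature,inactive,0.80
utility.literature,moderate,0.87
utility.literature,recommended,0.91
utility.condition,colorectal_cancer,0.786
utility.condition,chd,0.735
utility.condition,t2d,0.785
utility.condition,stroke,0.62
utility.condition,depression,0.57
annual_cost.societal,inactive,2436
annual_cost.societal,moderate,1506
annual_cost.societal,recommended,1997
annual_cost.societal,colorectal_cancer,34085
annual_cost.societal,chd,5239
annual_cost.societal,t2d,5907
annual_cost.societal,stroke,24979
annual_cost.societal,depression,6819
annual_cost.healthcare,inactive,1107
annual_cost.healthcare,moderate,594
annual_cost.healthcare,recommended,747
annual_cost.healthcare,colorectal_cancer,25346
annual_cost.healthcare,chd,1954
annual_cost.healthcare,t2d,3089
annual_cost.healthcare,stroke,18750
annual_cost.healthcare,depression,966
program_cost,eurofit_program,260
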
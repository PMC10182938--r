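group,metric,stat,value
children,CDI,min,0.21
children,CDI,mean,0.39
children,CDI,max,1
children,CDI,sd,0.11
children,HQ,min,0.35
children,HQ,mean,0.63
children,HQ,max,1.60
children,HQ,sd,0.19
teenagers,CDI,min,0.11
teenagers,CDI,mean,0.2
teenagers,CDI,max,0.51
teenagers,CDI,sd,0.06
teenagers,HQ,min,0.18
teenagers,HQ,mean,0.32
teenagers,HQ,max,0.83
teenagers,HQ,sd,0.10
adults,CDI,min,0.06
adults,CDI,mean,0.13
adults,CDI,max,0.33
adults,CDI,sd,0.03
adults,HQ,min,0.11
adults,HQ,mean,0.21
adults,HQ,max,0.53
adults,HQ,sd,0.06
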
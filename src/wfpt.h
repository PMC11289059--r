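#ifndef PRTDDM_WFPT_H
#define PRTDDM_WFPT_H

double wfpt_logf_lower(double t, double v, double a, double w,
                       double s, double eps);
double wfpt_logf(double t, int upper, double v, double a, double w,
                 double s, double eps);

#endif
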
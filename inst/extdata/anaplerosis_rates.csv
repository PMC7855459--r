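strain,mu,mu_err,pi_glc,pi_glc_err,pi_co2,pi_co2_err,theta_published,theta_err_published
ATCC 13032 (WT),0.45,0.04,4.82,0.25,6.94,0.71,0.82,0.089
dpck,0.38,0.02,4.10,0.14,5.51,0.53,0.81,0.077
dppc,0.45,0.04,5.12,0.24,7.64,1.09,0.79,0.083
dpyc,0.40,0.02,4.65,0.17,7.43,0.76,0.80,0.072
dmalE,0.46,0.02,4.88,0.17,7.00,1.00,0.84,0.080
dpck dmalE,0.46,0.04,4.85,0.24,7.27,0.83,0.83,0.087
dppc dmalE,0.43,0.03,4.84,0.25,6.79,1.92,0.79,0.088
dpyc dodx,0.40,0.02,4.38,0.17,6.31,0.99,0.81,0.078
dppc dpyc (evolved),0.27,0.01,3.74,0.16,7.40,0.68,0.78,0.070
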
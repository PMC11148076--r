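species,flow,treatment,light,trait,mean,sd,n
Acropora cytherea,low,control,light,thickness_o2,104,29,9
Acropora cytherea,low,control,light,thickness_h,119,38,8
Acropora cytherea,low,control,light,delta_o2,73.8,25.2,9
Acropora cytherea,low,control,light,delta_ph,0.05,0.02,8
Acropora cytherea,low,control,light,flux_o2,0.53,0.16,9
Acropora cytherea,low,control,dark,thickness_o2,101,33,9
Acropora cytherea,low,control,dark,thickness_h,102,80,8
Acropora cytherea,low,control,dark,delta_o2,-45.7,16.5,9
Acropora cytherea,low,control,dark,delta_ph,-0.02,0.01,8
Acropora cytherea,low,control,dark,flux_o2,-0.38,0.13,9
Acropora cytherea,moderate,control,light,thickness_o2,79,56,9
Acropora cytherea,moderate,control,light,thickness_h,88,46,8
Acropora cytherea,moderate,control,light,delta_o2,67.2,34.6,9
Acropora cytherea,moderate,control,light,delta_ph,0.03,0.02,8
Acropora cytherea,moderate,control,light,flux_o2,0.67,0.25,9
Acropora cytherea,moderate,control,dark,thickness_o2,81,46,9
Acropora cytherea,moderate,control,dark,thickness_h,65,28,8
Acropora cytherea,moderate,control,dark,delta_o2,-45.4,25.2,9
Acropora cytherea,moderate,control,dark,delta_ph,-0.02,0.01,8
Acropora cytherea,moderate,control,dark,flux_o2,-0.53,0.23,9
Acropora cytherea,low,OA,light,thickness_o2,202,101,9
Acropora cytherea,low,OA,light,thickness_h,137,45,9
Acropora cytherea,low,OA,light,delta_o2,73.4,25.9,9
Acropora cytherea,low,OA,light,delta_ph,0.05,0.03,9
Acropora cytherea,low,OA,light,flux_o2,0.32,0.16,9
Acropora cytherea,low,OA,dark,thickness_o2,203,92,9
Acropora cytherea,low,OA,dark,thickness_h,120,54,9
Acropora cytherea,low,OA,dark,delta_o2,-46.1,14.3,9
Acropora cytherea,low,OA,dark,delta_ph,-0.03,0.01,9
Acropora cytherea,low,OA,dark,flux_o2,-0.23,0.12,9
Acropora cytherea,moderate,OA,light,thickness_o2,108,45,9
Acropora cytherea,moderate,OA,light,thickness_h,70,25,9
Acropora cytherea,moderate,OA,light,delta_o2,57.0,29.4,9
Acropora cytherea,moderate,OA,light,delta_ph,0.02,0.01,9
Acropora cytherea,moderate,OA,light,flux_o2,0.41,0.28,9
Acropora cytherea,moderate,OA,dark,thickness_o2,111,44,9
Acropora cytherea,moderate,OA,dark,thickness_h,100,68,9
Acropora cytherea,moderate,OA,dark,delta_o2,-40.5,17.4,9
Acropora cytherea,moderate,OA,dark,delta_ph,-0.01,0.00,9
Acropora cytherea,moderate,OA,dark,flux_o2,-0.35,0.13,9
Pocillopora verrucosa,low,control,light,thickness_o2,201,93,9
Pocillopora verrucosa,low,control,light,delta_o2,94.7,42.2,9
Pocillopora verrucosa,low,control,light,flux_o2,0.68,0.44,9
Pocillopora verrucosa,low,control,dark,thickness_o2,209,75,9
Pocillopora verrucosa,low,control,dark,delta_o2,-87.5,18.5,9
Pocillopora verrucosa,low,control,dark,flux_o2,-0.45,0.20,9
Pocillopora verrucosa,moderate,control,light,thickness_o2,118,60,9
Pocillopora verrucosa,moderate,control,light,delta_o2,58.7,43.4,9
Pocillopora verrucosa,moderate,control,light,flux_o2,0.48,0.20,9
Pocillopora verrucosa,moderate,control,dark,thickness_o2,108,37,9
Pocillopora verrucosa,moderate,control,dark,delta_o2,-72.5,23.8,9
Pocillopora verrucosa,moderate,control,dark,flux_o2,-0.63,0.21,9
Pocillopora verrucosa,low,OA,light,thickness_o2,211,82,9
Pocillopora verrucosa,low,OA,light,thickness_h,148,99,9
Pocillopora verrucosa,low,OA,light,delta_o2,101.9,40.6,9
Pocillopora verrucosa,low,OA,light,delta_ph,0.02,0.04,9
Pocillopora verrucosa,low,OA,light,flux_o2,0.51,0.29,9
Pocillopora verrucosa,low,OA,dark,thickness_o2,166,29,9
Pocillopora verrucosa,low,OA,dark,thickness_h,144,55,9
Pocillopora verrucosa,low,OA,dark,delta_o2,-86.2,25.1,9
Pocillopora verrucosa,low,OA,dark,delta_ph,-0.09,0.05,9
Pocillopora verrucosa,low,OA,dark,flux_o2,-0.45,0.13,9
Pocillopora verrucosa,moderate,OA,light,thickness_o2,155,64,9
Pocillopora verrucosa,moderate,OA,light,thickness_h,57,37,9
Pocillopora verrucosa,moderate,OA,light,delta_o2,52.6,22.3,9
Pocillopora verrucosa,moderate,OA,light,delta_ph,0.01,0.01,9
Pocillopora verrucosa,moderate,OA,light,flux_o2,0.37,0.21,9
Pocillopora verrucosa,moderate,OA,dark,thickness_o2,129,74,9
Pocillopora verrucosa,moderate,OA,dark,thickness_h,76,31,9
Pocillopora verrucosa,moderate,OA,dark,delta_o2,-67.1,16.4,9
Pocillopora verrucosa,moderate,OA,dark,delta_ph,-0.05,0.04,9
Pocillopora verrucosa,moderate,OA,dark,flux_o2,-0.51,0.15,9
Porites cylindrica,low,control,light,thickness_o2,282,196,9
Porites cylindrica,low,control,light,delta_o2,96.6,28.5,9
Porites cylindrica,low,control,light,flux_o2,0.39,0.23,9
Porites cylindrica,low,control,dark,thickness_o2,287,170,9
Porites cylindrica,low,control,dark,delta_o2,-57.2,15.0,9
Porites cylindrica,low,control,dark,flux_o2,-0.20,0.16,9
Porites cylindrica,moderate,control,light,thickness_o2,102,34,9
Porites cylindrica,moderate,control,light,delta_o2,78.8,29.8,9
Porites cylindrica,moderate,control,light,flux_o2,0.65,0.28,9
Porites cylindrica,moderate,control,dark,thickness_o2,106,39,9
Porites cylindrica,moderate,control,dark,delta_o2,-44.3,15.8,9
Porites cylindrica,moderate,control,dark,flux_o2,-0.37,0.15,9
Porites cylindrica,low,OA,light,thickness_o2,252,140,9
Porites cylindrica,low,OA,light,thickness_h,119,44,9
Porites cylindrica,low,OA,light,delta_o2,100.1,53.5,9
Porites cylindrica,low,OA,light,delta_ph,0.04,0.02,9
Porites cylindrica,low,OA,light,flux_o2,0.43,0.45,9
Porites cylindrica,low,OA,dark,thickness_o2,287,166,9
Porites cylindrica,low,OA,dark,thickness_h,128,62,9
Porites cylindrica,low,OA,dark,delta_o2,-44.0,12.7,9
Porites cylindrica,low,OA,dark,delta_ph,-0.05,0.03,9
Porites cylindrica,low,OA,dark,flux_o2,-0.17,0.13,9
Porites cylindrica,moderate,OA,light,thickness_o2,117,81,9
Porites cylindrica,moderate,OA,light,thickness_h,81,50,9
Porites cylindrica,moderate,OA,light,delta_o2,83.1,37.3,9
Porites cylindrica,moderate,OA,light,delta_ph,0.02,0.01,9
Porites cylindrica,moderate,OA,light,flux_o2,0.78,0.60,9
Porites cylindrica,moderate,OA,dark,thickness_o2,104,58,9
Porites cylindrica,moderate,OA,dark,thickness_h,86,36,9
Porites cylindrica,moderate,OA,dark,delta_o2,-37.9,11.3,9
Porites cylindrica,moderate,OA,dark,delta_ph,-0.02,0.01,9
Porites cylindrica,moderate,OA,dark,flux_o2,-0.34,0.08,9
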
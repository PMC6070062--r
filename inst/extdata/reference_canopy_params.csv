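# Fitted two-state switching-rate parameters and LAI for 15 reference
# canopies (wheat and Bambara groundnut assemblies, labels A-O):
# A original wheat plant; B-D the same plant rotated 90/180/270 deg;
# E-H the plant randomly rotated on a 3x3 lattice at spacings 200/150/125/100 mm;
# I replica plant, same line; J-K plants from two other wheat lines;
# L-N Bambara groundnut 39 d after sowing; O Bambara groundnut 80 d.
canopy,lai,a_on,b1_on,b2_on,a_off,b1_off,b2_off
A,0.69,0.85,3.83,0.031,1.0,1.75,0.099
B,0.69,0.85,4.19,0.043,1.0,1.54,0.10
C,0.69,0.85,4.40,0.017,1.0,2.12,0.087
D,0.69,0.85,4.35,0.057,1.0,2.01,0.099
E,1.15,0.79,3.29,0.063,0.94,1.92,0.24
F,2.11,0.62,3.32,-0.017,0.99,4.83,0.38
G,2.89,0.54,3.17,-0.021,0.99,5.58,0.43
H,4.18,0.34,2.14,-0.026,1.0,8.29,0.55
I,1.23,0.78,1.73,0.047,1.0,1.36,0.072
J,0.76,0.66,2.39,0.096,1.0,1.053,0.19
K,1.32,0.64,1.77,0.051,0.99,1.33,0.16
L,0.49,0.62,0.42,0.012,0.55,1.04,0.016
M,0.38,0.73,0.65,0.019,0.51,1.13,0.0075
N,0.39,0.98,0.36,0.025,0.93,1.17,0.0095
O,0.79,0.94,1.034,0.0037,0.43,0.9,0.0033
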
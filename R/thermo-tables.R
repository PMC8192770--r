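# Nearest-neighbor thermodynamic parameter tables for DNA duplexes.
#
# Watson-Crick stack parameters are the unified oligonucleotide values of
# SantaLucia (1998) / SantaLucia & Hicks (2004). Internal single-mismatch
# stack parameters are the published compilation of Allawi & SantaLucia
# (1997, 1998a-c) and Peyret et al. (1999). Keys are "XY/UV": top-strand
# dinucleotide 5'->3' over the two bottom-strand bases lying under X and Y
# (bottom strand read 3'->5'). dH in kcal/mol, dS in cal/(mol K).
# Tables are expanded to include the rotationally equivalent key of every
# published stack ("XY/UV" == reverse(UV)/reverse(XY)).

.NN_DH <- c(
  "AA/TT" = -7.9, "AC/TG" = -8.4, "AG/TC" = -7.8, "AT/TA" = -7.2,
  "CA/GT" = -8.5, "CC/GG" = -8.0, "CG/GC" = -10.6, "CT/GA" = -7.8,
  "GA/CT" = -8.2, "GC/CG" = -9.8, "GG/CC" = -8.0, "GT/CA" = -8.4,
  "TA/AT" = -7.2, "TC/AG" = -8.2, "TG/AC" = -8.5, "TT/AA" = -7.9
)

.NN_DS <- c(
  "AA/TT" = -22.2, "AC/TG" = -22.4, "AG/TC" = -21.0, "AT/TA" = -20.4,
  "CA/GT" = -22.7, "CC/GG" = -19.9, "CG/GC" = -27.2, "CT/GA" = -21.0,
  "GA/CT" = -22.2, "GC/CG" = -24.4, "GG/CC" = -19.9, "GT/CA" = -22.4,
  "TA/AT" = -21.3, "TC/AG" = -22.2, "TG/AC" = -22.7, "TT/AA" = -22.2
)

# internal single-mismatch stacks (one WC pair + one mismatched pair)
.MM_DH <- c(
  "AA/AT" = 4.7, "AA/CT" = 7.6, "AA/GT" = 3.0, "AA/IT" = -3.4,
  "AA/TA" = 1.2, "AA/TC" = 2.3, "AA/TG" = -0.6, "AA/TI" = -0.7,
  "AC/AG" = -2.9, "AC/CG" = -0.7, "AC/GG" = 0.5, "AC/IG" = -7.8,
  "AC/TA" = 5.3, "AC/TC" = 0.0, "AC/TI" = -8.8, "AC/TT" = 0.7,
  "AG/AC" = -0.9, "AG/CC" = 0.6, "AG/GC" = -4.0, "AG/IC" = 2.6,
  "AG/TA" = -0.7, "AG/TG" = -3.1, "AG/TI" = 0.1, "AG/TT" = 1.0,
  "AI/TA" = -8.3, "AI/TC" = -8.9, "AI/TG" = -4.9, "AI/TI" = -3.3,
  "AI/TT" = 0.49, "AT/AA" = 1.2, "AT/CA" = 5.3, "AT/GA" = -0.7,
  "AT/IA" = -8.3, "AT/TC" = -1.2, "AT/TG" = -2.5, "AT/TI" = -5.6,
  "AT/TT" = -2.7, "CA/AT" = 3.4, "CA/CT" = 6.1, "CA/GA" = -0.9,
  "CA/GC" = 1.9, "CA/GG" = -0.7, "CA/GI" = -7.0, "CA/IT" = -5.9,
  "CA/TT" = 1.0, "CC/AG" = 5.2, "CC/CG" = 3.6, "CC/GA" = 0.6,
  "CC/GC" = -1.5, "CC/GI" = -8.3, "CC/GT" = -0.8, "CC/IG" = -6.8,
  "CC/TG" = 5.2, "CG/AC" = 1.9, "CG/CC" = -1.5, "CG/GA" = -4.0,
  "CG/GG" = -4.9, "CG/GI" = 5.8, "CG/GT" = -4.1, "CG/IC" = -5.4,
  "CG/TC" = -1.5, "CI/GA" = 2.6, "CI/GC" = -5.4, "CI/GG" = 7.1,
  "CI/GI" = 1.3, "CI/GT" = -1.0, "CT/AA" = 2.3, "CT/CA" = 0.0,
  "CT/GC" = -1.5, "CT/GG" = -2.8, "CT/GI" = 0.1, "CT/GT" = -5.0,
  "CT/IA" = -8.9, "CT/TA" = -1.2, "GA/AT" = 0.7, "GA/CA" = -2.9,
  "GA/CC" = 5.2, "GA/CG" = -0.6, "GA/CI" = -7.6, "GA/GT" = 1.6,
  "GA/IT" = -1.9, "GA/TT" = -1.3, "GC/AG" = -0.6, "GC/CA" = -0.7,
  "GC/CC" = 3.6, "GC/CI" = -5.0, "GC/CT" = 2.3, "GC/GG" = -6.0,
  "GC/IG" = -1.1, "GC/TG" = -4.4, "GG/AC" = -0.7, "GG/CA" = 0.5,
  "GG/CG" = -6.0, "GG/CI" = -7.6, "GG/CT" = 3.3, "GG/GC" = -4.9,
  "GG/IC" = 7.1, "GG/TC" = -2.8, "GG/TT" = 5.8, "GI/CA" = -7.8,
  "GI/CC" = -6.8, "GI/CG" = -1.1, "GI/CI" = -0.5, "GI/CT" = -3.5,
  "GT/AA" = -0.6, "GT/CC" = 5.2, "GT/CG" = -4.4, "GT/CI" = -4.3,
  "GT/CT" = -2.2, "GT/GA" = -3.1, "GT/IA" = -4.9, "GT/TA" = -2.5,
  "GT/TG" = 4.1, "IA/AT" = -1.3, "IA/CT" = -4.9, "IA/GT" = 1.0,
  "IA/IT" = 0.1, "IA/TT" = -0.8, "IC/AG" = -7.6, "IC/CG" = -5.0,
  "IC/GG" = -7.6, "IC/IG" = -0.5, "IC/TG" = -4.3, "IG/AC" = -7.0,
  "IG/CC" = -8.3, "IG/GC" = 5.8, "IG/IC" = 1.3, "IG/TC" = 0.1,
  "IT/AA" = -0.7, "IT/CA" = -8.8, "IT/GA" = 0.1, "IT/IA" = -3.3,
  "IT/TA" = -5.6, "TA/AA" = 4.7, "TA/AC" = 3.4, "TA/AG" = 0.7,
  "TA/AI" = -1.3, "TA/CT" = 1.2, "TA/GT" = -0.1, "TA/IT" = -6.5,
  "TA/TT" = 0.2, "TC/AA" = 7.6, "TC/AC" = 6.1, "TC/AI" = -4.9,
  "TC/AT" = 1.2, "TC/CG" = 2.3, "TC/GG" = 3.3, "TC/IG" = -3.5,
  "TC/TG" = -2.2, "TG/AA" = 3.0, "TG/AG" = 1.6, "TG/AI" = 1.0,
  "TG/AT" = -0.1, "TG/CC" = -0.8, "TG/GC" = -4.1, "TG/GT" = -1.4,
  "TG/IC" = -1.0, "TG/TC" = -5.0, "TI/AA" = -3.4, "TI/AC" = -5.9,
  "TI/AG" = -1.9, "TI/AI" = 0.1, "TI/AT" = -6.5, "TT/AC" = 1.0,
  "TT/AG" = -1.3, "TT/AI" = -0.8, "TT/AT" = 0.2, "TT/CA" = 0.7,
  "TT/GA" = 1.0, "TT/GG" = 5.8, "TT/IA" = 0.49, "TT/TA" = -2.7
)

.MM_DS <- c(
  "AA/AT" = 12.9, "AA/CT" = 20.2, "AA/GT" = 7.4, "AA/IT" = -11.2,
  "AA/TA" = 1.7, "AA/TC" = 4.6, "AA/TG" = -2.3, "AA/TI" = -2.6,
  "AC/AG" = -9.8, "AC/CG" = -3.8, "AC/GG" = 3.2, "AC/IG" = -21.1,
  "AC/TA" = 14.6, "AC/TC" = -4.4, "AC/TI" = -25.4, "AC/TT" = 0.2,
  "AG/AC" = -4.2, "AG/CC" = -0.6, "AG/GC" = -13.2, "AG/IC" = 8.9,
  "AG/TA" = -2.3, "AG/TG" = -9.5, "AG/TI" = -1.8, "AG/TT" = 0.9,
  "AI/TA" = -25.0, "AI/TC" = -25.5, "AI/TG" = -15.8, "AI/TI" = -11.9,
  "AI/TT" = -0.7, "AT/AA" = 1.7, "AT/CA" = 14.6, "AT/GA" = -2.3,
  "AT/IA" = -25.0, "AT/TC" = -6.2, "AT/TG" = -8.3, "AT/TI" = -18.7,
  "AT/TT" = -10.8, "CA/AT" = 8.0, "CA/CT" = 16.4, "CA/GA" = -4.2,
  "CA/GC" = 3.7, "CA/GG" = -2.3, "CA/GI" = -20.0, "CA/IT" = -17.4,
  "CA/TT" = 0.7, "CC/AG" = 14.2, "CC/CG" = 8.9, "CC/GA" = -0.6,
  "CC/GC" = -7.2, "CC/GI" = -23.8, "CC/GT" = -4.5, "CC/IG" = -19.1,
  "CC/TG" = 13.5, "CG/AC" = 3.7, "CG/CC" = -7.2, "CG/GA" = -13.2,
  "CG/GG" = -15.3, "CG/GI" = 16.9, "CG/GT" = -11.7, "CG/IC" = -13.7,
  "CG/TC" = -6.1, "CI/GA" = 8.9, "CI/GC" = -13.7, "CI/GG" = 21.3,
  "CI/GI" = 3.0, "CI/GT" = -2.4, "CT/AA" = 4.6, "CT/CA" = -4.4,
  "CT/GC" = -6.1, "CT/GG" = -8.0, "CT/GI" = -1.0, "CT/GT" = -15.8,
  "CT/IA" = -25.5, "CT/TA" = -6.2, "GA/AT" = 0.7, "GA/CA" = -9.8,
  "GA/CC" = 14.2, "GA/CG" = -1.0, "GA/CI" = -20.2, "GA/GT" = 3.6,
  "GA/IT" = -8.5, "GA/TT" = -5.3, "GC/AG" = -1.0, "GC/CA" = -3.8,
  "GC/CC" = 8.9, "GC/CI" = -12.6, "GC/CT" = 5.4, "GC/GG" = -15.8,
  "GC/IG" = -3.2, "GC/TG" = -12.3, "GG/AC" = -2.3, "GG/CA" = 3.2,
  "GG/CG" = -15.8, "GG/CI" = -22.0, "GG/CT" = 10.4, "GG/GC" = -15.3,
  "GG/IC" = 21.3, "GG/TC" = -8.0, "GG/TT" = 16.3, "GI/CA" = -21.1,
  "GI/CC" = -19.1, "GI/CG" = -3.2, "GI/CI" = -1.3, "GI/CT" = -10.6,
  "GT/AA" = -2.3, "GT/CC" = 13.5, "GT/CG" = -12.3, "GT/CI" = -12.1,
  "GT/CT" = -8.4, "GT/GA" = -9.5, "GT/IA" = -15.8, "GT/TA" = -8.3,
  "GT/TG" = 9.5, "IA/AT" = -4.6, "IA/CT" = -13.9, "IA/GT" = 1.0,
  "IA/IT" = -2.3, "IA/TT" = -4.3, "IC/AG" = -20.2, "IC/CG" = -12.6,
  "IC/GG" = -22.0, "IC/IG" = -1.3, "IC/TG" = -12.1, "IG/AC" = -20.0,
  "IG/CC" = -23.8, "IG/GC" = 16.9, "IG/IC" = 3.0, "IG/TC" = -1.0,
  "IT/AA" = -2.6, "IT/CA" = -25.4, "IT/GA" = -1.8, "IT/IA" = -11.9,
  "IT/TA" = -18.7, "TA/AA" = 12.9, "TA/AC" = 8.0, "TA/AG" = 0.7,
  "TA/AI" = -4.6, "TA/CT" = 0.7, "TA/GT" = -1.7, "TA/IT" = -22.0,
  "TA/TT" = -1.5, "TC/AA" = 20.2, "TC/AC" = 16.4, "TC/AI" = -13.9,
  "TC/AT" = 0.7, "TC/CG" = 5.4, "TC/GG" = 10.4, "TC/IG" = -10.6,
  "TC/TG" = -8.4, "TG/AA" = 7.4, "TG/AG" = 3.6, "TG/AI" = 1.0,
  "TG/AT" = -1.7, "TG/CC" = -4.5, "TG/GC" = -11.7, "TG/GT" = -6.2,
  "TG/IC" = -2.4, "TG/TC" = -15.8, "TI/AA" = -11.2, "TI/AC" = -17.4,
  "TI/AG" = -8.5, "TI/AI" = -2.3, "TI/AT" = -22.0, "TT/AC" = 0.7,
  "TT/AG" = -5.3, "TT/AI" = -4.3, "TT/AT" = -1.5, "TT/CA" = 0.2,
  "TT/GA" = 0.9, "TT/GG" = 16.3, "TT/IA" = -0.7, "TT/TA" = -10.8
)

# duplex initiation terms, by terminal base pair class
.INIT_DH <- c(AT = 2.3, GC = 0.1)
.INIT_DS <- c(AT = 4.1, GC = -2.8)
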
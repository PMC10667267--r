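# Reference QED values for 10 standard drugs, computed once with RDKit
# 2024.09.2 (rdkit.Chem.QED) from the SMILES of each drug; the descriptor
# vectors below are RDKit's own property values, so the comparison isolates
# the desirability/geometric-mean arithmetic from descriptor calculation.
qed_reference <- tibble::tribble(
  ~name,           ~MW,     ~ALOGP,   ~HBA, ~HBD, ~TPSA,  ~ROTB, ~AROM, ~ALERTS, ~qed_weighted,  ~qed_unweighted, ~qed_max,
  "aspirin",       180.159,  1.3101,  4,    1,    63.6,   2,     1,     2,       0.5501217967,   0.6734029196,    0.4914628987,
  "caffeine",      194.194, -1.0293,  3,    0,    61.82,  0,     2,     0,       0.5384628262,   0.5932138843,    0.5580069736,
  "ibuprofen",     206.285,  3.0732,  2,    1,    37.3,   4,     1,     0,       0.8215995487,   0.8514261462,    0.8176682665,
  "acetaminophen", 151.165,  1.3506,  2,    2,    49.33,  1,     1,     1,       0.5950261968,   0.6803910898,    0.5790101148,
  "atorvastatin",  558.65,   6.3136,  5,    4,    111.79, 12,    4,     0,       0.1627604393,   0.1890885956,    0.1966113754,
  "sildenafil",    474.587,  1.6109,  7,    1,    113.42, 7,     3,     0,       0.5534046105,   0.5080720219,    0.5912155533,
  "omeprazole",    345.424,  2.89974, 5,    1,    77.1,   5,     3,     0,       0.7692390366,   0.7545860133,    0.8032529293,
  "warfarin",      308.333,  3.6096,  4,    1,    67.51,  4,     3,     1,       0.7476258148,   0.7719140260,    0.7600515794,
  "metformin",     129.167, -1.03416, 3,    4,    88.99,  0,     0,     2,       0.2487848389,   0.3370357644,    0.2339203467,
  "diazepam",      284.746,  3.1538,  1,    0,    32.67,  1,     2,     0,       0.7916453362,   0.6994889002,    0.7931771798
)
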
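# Atom/bond featurization and SMILES graph construction.
#
# Expected feature values below were computed with a reference
# cheminformatics toolkit (RDKit 2024.09) on the same molecules and frozen
# as literals.

# feature layout offsets
DEG0 <- 44L; TOTH0 <- 55L; IMPH0 <- 66L; AROM <- 78L
BT <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
CONJ_F <- 5L; CONJ_T <- 6L; RING_F <- 7L; RING_T <- 8L
STEREO0 <- 8L  # none = 9, any = 10, Z = 11, E = 12, cis = 13, trans = 14

hot <- function(v) which(v == 1)

test_that("atom features encode element, degree, hydrogen counts and aromaticity", {
  benz <- smiles_to_graph("c1ccccc1")
  expect_equal(benz$atom_count, 6L)
  af <- benz$atom_features[1L, ]
  expect_length(af, 78L)
  # aromatic carbon: element C, heavy degree 2, total H 1, implicit H 1
  expect_equal(hot(af), c(1L, DEG0 + 3L, TOTH0 + 2L, IMPH0 + 2L, AROM))

  meth <- smiles_to_graph("C")
  af <- meth$atom_features[1L, ]
  # methane: degree 0, 4 total and implicit hydrogens, not aromatic
  expect_equal(hot(af), c(1L, DEG0 + 1L, TOTH0 + 5L, IMPH0 + 5L))

  eth <- smiles_to_graph("CCO")
  # ethanol: C(3H), C(2H), O(1H)
  expect_equal(eth$atoms$element, c("C", "C", "O"))
  expect_equal(eth$atoms$degree, c(1L, 2L, 1L))
  expect_equal(eth$atoms$total_h, c(3L, 2L, 1L))
  expect_equal(eth$atoms$implicit_h, c(3L, 2L, 1L))
  expect_false(any(eth$atoms$aromatic))
})

test_that("out-of-vocabulary elements map to the reserved final slot", {
  f <- featurize_atom(list(element = "Xx", degree = 1, total_h = 0,
                           implicit_h = 0, aromatic = FALSE))
  expect_equal(which(f[1:44] == 1), 44L)
  # counts above 10 clamp into the last slot
  f2 <- featurize_atom(list(element = "C", degree = 14, total_h = 12,
                            implicit_h = 11, aromatic = TRUE))
  expect_equal(hot(f2), c(1L, DEG0 + 11L, TOTH0 + 11L, IMPH0 + 11L, AROM))
})

test_that("bond features encode type, conjugation, ring membership and stereo", {
  ethane <- smiles_to_graph("CC")
  bf <- ethane$bond_features[1L, ]
  expect_length(bf, 14L)
  expect_equal(hot(bf), c(BT["single"], CONJ_F, RING_F, STEREO0 + 1L),
               ignore_attr = TRUE)

  benz <- smiles_to_graph("c1ccccc1")
  bf <- benz$bond_features[1L, ]
  expect_equal(hot(bf), c(BT["aromatic"], CONJ_T, RING_T, STEREO0 + 1L),
               ignore_attr = TRUE)

  tb <- smiles_to_graph("C/C=C/C")   # trans-2-butene
  expect_equal(tb$bonds$stereo, c("none", "E", "none"))
  cb <- smiles_to_graph("C/C=C\\C")  # cis-2-butene
  expect_equal(cb$bonds$stereo, c("none", "Z", "none"))
  db <- tb$bonds$type == "double"
  expect_equal(hot(tb$bond_features[2L * which(db) - 1L, ]),
               c(BT["double"], CONJ_F, RING_F, STEREO0 + 4L),
               ignore_attr = TRUE)
})

test_that("conjugation perception matches the reference toolkit on known cases", {
  cases <- list(
    # smiles, per-bond conjugated flags in bond order (RDKit 2024.09)
    list("CC", FALSE),
    list("C=C", FALSE),
    list("C=CC=C", c(TRUE, TRUE, TRUE)),
    list("CC(=O)N", c(FALSE, TRUE, TRUE)),       # amide
    list("CC(=O)OC", c(FALSE, TRUE, TRUE, FALSE)), # ester
    list("C=COC", c(TRUE, TRUE, FALSE)),         # enol ether
    list("CC#N", c(FALSE, FALSE)),               # nitrile
    list("Cc1ccccc1", c(FALSE, rep(TRUE, 6L))))  # toluene
  for (cs in cases) {
    g <- smiles_to_graph(cs[[1L]])
    expect_equal(g$bonds$conjugated, cs[[2L]], info = cs[[1L]])
  }
})

test_that("smiles_to_graph builds both directed orientations with shared features", {
  g <- smiles_to_graph("CCO")
  expect_equal(g$atom_count, 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(nrow(g$directed_bonds), 4L)
  # each undirected bond appears in both orientations with identical features
  for (b in seq_len(nrow(g$bonds))) {
    expect_equal(g$directed_bonds[2L * b - 1L, ],
                 g$directed_bonds[2L * b, c(2L, 1L)], ignore_attr = TRUE)
    expect_equal(g$bond_features[2L * b - 1L, ], g$bond_features[2L * b, ])
  }
  # single-atom molecule: empty bond matrices are permitted
  g1 <- smiles_to_graph("C")
  expect_equal(g1$atom_count, 1L)
  expect_equal(nrow(g1$directed_bonds), 0L)
  expect_equal(dim(g1$bond_features), c(0L, 14L))
})

test_that("malformed SMILES raise a parse failure naming the string", {
  expect_error(smiles_to_graph("C("), "C\\(")
  expect_error(smiles_to_graph("C(Cl"), "parse failure")
  expect_error(smiles_to_graph("C1CC"), "ring")
  expect_error(smiles_to_graph(""), "parse failure")
  expect_error(smiles_to_graph("CC)"), "parse failure")
  errs <- smiles_to_graphs(c("CC", "C(", "CCO"), on_error = "null")
  expect_null(errs[[2L]])
  expect_s3_class(errs[[1L]], "mol_graph")
  expect_match(attr(errs, "errors")[2L], "C\\(")
})

test_that("atom feature rows have exactly one 1 per one-hot block", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "C1CCCCC1",
            "c1cc[nH]c1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "N#Cc1ccccc1",
            "O=S(=O)(N)c1ccccc1", "BrCCl", "[Na+].[Cl-]")
  for (smi in smis) {
    g <- tryCatch(smiles_to_graph(smi), error = function(e) NULL)
    if (is.null(g)) next
    rs <- rowSums(g$atom_features)
    expect_true(all(rs %in% c(4, 5)), info = smi)
    for (block in list(1:44, 45:55, 56:66, 67:77)) {
      expect_true(all(rowSums(g$atom_features[, block, drop = FALSE]) == 1),
                  info = smi)
    }
    if (nrow(g$bond_features)) {
      expect_true(all(rowSums(g$bond_features) == 4), info = smi)
    }
  }
})

test_that("parsing is deterministic", {
  g1 <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1")
  g2 <- smiles_to_graph("CC(=O)Nc1ccc(O)cc1")
  expect_identical(g1$atom_features, g2$atom_features)
  expect_identical(g1$bond_features, g2$bond_features)
  expect_identical(g1$directed_bonds, g2$directed_bonds)
})
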
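# Small in-code fixtures shared across test files.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# toy networks as model-CSV text
toy_linear_model <- function() {
  write_tmp(c(
    "id,equation,reversible,block",
    "v1,A.ext (ab) -> A (ab),FALSE,base",
    "v2,A (ab) -> B (ab),FALSE,base",
    "v3,B (ab) -> B.ext (ab),FALSE,base"
  ), ".csv")
}

toy_condensation_model <- function() {
  write_tmp(c(
    "id,equation,reversible,block",
    "u1,X.ext (a) -> X (a),FALSE,base",
    "u2,Y.ext (b) -> Y (b),FALSE,base",
    "u3,X (a) + Y (b) -> C (ab),FALSE,base",
    "u4,C (ab) -> C.ext (ab),FALSE,base"
  ), ".csv")
}

# 4 balanced metabolites, one reversible cleavage, one condensation: used for
# EMU-vs-oracle sweeps
toy_cycle_model <- function() {
  write_tmp(c(
    "id,equation,reversible,block",
    "r1,S.ext (abc) -> S (abc),FALSE,base",
    "r2,S (abc) -> P (ab) + Q (c),TRUE,base",
    "r3,P (ab) + Q (c) -> T (cab),FALSE,base",
    "r4,T (abc) -> T.ext (abc),FALSE,base",
    "r5,P (ab) -> P.ext (ab),FALSE,base",
    "r6,Q (a) -> Q.ext (a),FALSE,base"
  ), ".csv")
}

expect_mdv_valid <- function(mdv, tol = 1e-9) {
  expect_true(all(mdv >= -1e-12))
  expect_equal(sum(mdv), 1, tolerance = tol)
}

# topology equality for unrooted trees
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
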
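# Shared helpers: tiny deterministic fixtures and brute-force oracles.

# All permutations of 1..n as a matrix (n! rows); used for exhaustive
# enumeration of small rank-column spaces.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

# A tiny fixed two-group study with known values (3 probes, 2v2).
tiny_study <- function() {
  m <- matrix(c(
    5, 6, 1, 2,    # strongly up
    3, 3, 3.5, 3,  # flat-ish
    1, 2, 6, 5     # strongly down
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("pA", "pB", "pC"), c("c1", "c2", "n1", "n2")))
  expression_study(m, group = c("case", "case", "control", "control"),
                   symbols = c("A", "B", "C"), study_name = "tiny")
}

# A symbol-level gene list for meta-comparison fixtures.
make_list <- function(symbols, study, direction) {
  gene_list(symbols, study = study, direction = direction)
}

# Deterministic noise-free qPCR plate from per-group CT means.
manual_plate <- function(ct_case, ct_control, efficiencies,
                         reference_genes, n_case = 3, n_control = 3) {
  genes <- names(ct_case)
  rows <- list()
  for (g in genes) {
    for (s in seq_len(n_case)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, sample = paste0("case_", s), group = "case",
        replicate = 1:3, ct = ct_case[[g]])
    }
    for (s in seq_len(n_control)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, sample = paste0("ctrl_", s), group = "control",
        replicate = 1:3, ct = ct_control[[g]])
    }
  }
  qpcr_plate(dplyr::bind_rows(rows), efficiencies = efficiencies,
             reference_genes = reference_genes)
}
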
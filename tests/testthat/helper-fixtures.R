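# small reusable fixtures, generated in code

# compact planted cohort for fast end-to-end unit tests
small_cohort <- function(seed = 7, delta = 1.5, n_per_class = 30,
                         n_genes = 400, n_pathways = 10, n_planted = 2,
                         coherence = 1) {
  spec <- synthetic_spec(n_genes = n_genes, n_pathways = n_pathways,
                         size_range = c(5L, 15L), n_planted = n_planted,
                         delta = delta, coherence = coherence,
                         n_normal = n_per_class, n_tumor = n_per_class,
                         seed = seed)
  simulate_cohort(spec)
}

# write a matrix as a TSV expression file and return the path
tmp_expr_file <- function(m, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_expression(m, path, ...)
  path
}

tmp_lines_file <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
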
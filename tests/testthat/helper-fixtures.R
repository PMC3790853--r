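# Shared fixture builders. Everything is generated in code, seeded, and small.

# locus table for n members of a family laid end-to-end on one chromosome
make_members <- function(n, len, family_id = "famA", chrom = "chr1",
                         strand = "+") {
  data.frame(family_id = family_id,
             seq_name = paste0(family_id, "_p", seq_len(n)),
             chrom = chrom,
             start = (seq_len(n) - 1L) * (len + 1000L),
             end = (seq_len(n) - 1L) * (len + 1000L) + len,
             strand = strand,
             stringsAsFactors = FALSE)
}

# aligned_family straight from a character matrix of gapless sequences
make_family <- function(strings, family_id = "famA") {
  mat <- do.call(rbind, strsplit(toupper(strings), ""))
  rownames(mat) <- names(strings) %||%
    paste0(family_id, "_p", seq_along(strings))
  members <- make_members(nrow(mat), ncol(mat), family_id)
  members$seq_name <- rownames(mat)
  igcscan:::new_aligned_family(family_id, mat, members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random gapless alignment of n x L with controlled mismatch rate to row 1
random_alignment <- function(n, L, mismatch = 0.05, seed = 1) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(rep(base, each = n), nrow = n)
  for (i in 2:n) {
    hit <- which(runif(L) < mismatch)
    mat[i, hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
  }
  rownames(mat) <- paste0("s", seq_len(n))
  mat
}

# quartet_result built by hand from (columns, labels, alt)
make_quartet_result <- function(columns, labels, alt = NULL,
                                dominant = "AB|CD",
                                leaves = c("a", "b", "c", "d")) {
  if (is.null(alt)) alt <- ifelse(labels == "R", "AC|BD", NA_character_)
  structure(list(leaves = leaves, dominant = dominant, columns = columns,
                 labels = labels, alt = alt,
                 n_C = sum(labels == "C"), n_R = sum(labels == "R"),
                 n_B = sum(labels == "B")),
            class = "quartet_result")
}

# small cached null family used across tests (6 paralogs, 5 kb, 95% identity)
shared_null_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- family_gen_spec(n_paralogs = 6, length = 5000,
                              target_identity = 0.95, seed = 42)
      cache <<- generate_null_family(spec, "shared")
    }
    cache
  }
})
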
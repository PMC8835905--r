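# Shared fixtures, built in code.

default_panel <- mindspike::mind_panel()

# Small mature reference set reused across tests.
tiny_refs <- mindspike::simulate_mature_refs(40, seed = 101)

# Random DNA contig of length n.
random_contig <- function(n, seed) {
  mindspike:::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

# Read table for a vector of insert sequences: insert + adapter + padding.
reads_from_inserts <- function(inserts, adapter, read_len = 75,
                               qchar = "I") {
  full <- substr(paste0(inserts, adapter, strrep("A", read_len)),
                 1, read_len)
  data.frame(id = sprintf("r%03d", seq_along(full)), seq = full,
             qual = strrep(qchar, nchar(full)), stringsAsFactors = FALSE)
}
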
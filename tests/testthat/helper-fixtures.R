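# Shared fixtures, generated once per test run.

# small synthetic catalog with three contrasting IS types
test_catalog <- function() {
  if (is.null(.fixture_env$catalog))
    .fixture_env$catalog <- simulate_catalog(seed = 42)
  .fixture_env$catalog
}

.fixture_env <- new.env(parent = emptyenv())

# one-replicon tibble wrapper
as_replicon <- function(seq, id = "chr", kind = "chromosome") {
  tibble::tibble(id = id, kind = kind, seq = seq, length_bp = nchar(seq))
}

# minimal catalog row for search tests (search_nt only needs name+consensus)
query_catalog <- function(consensus, name = "Q") {
  tibble::tibble(name = name, consensus = consensus)
}

# reference-loci / per-sample call encoding of the bundled ISTth7 site table
sites_as_presence_inputs <- function(sites = istth7_softclip_sites()) {
  ref <- sites[sites$in_reference == "YES",
               c("replicon", "start", "end")]
  names(ref)[1] <- "replicon_id"
  ref$is_name <- "ISTth7"
  calls <- lapply(c(HB27A = "in_HB27A", HB27E = "in_HB27E"), function(col) {
    x <- sites[sites[[col]] == "YES", c("replicon", "start", "end")]
    names(x)[1] <- "replicon_id"
    x$is_name <- "ISTth7"
    x
  })
  list(reference = ref, calls = calls)
}
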
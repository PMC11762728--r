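# Shared fixtures, all generated in code.

toy_newick <- "((A:3,B:3):7,C:10);"

toy_tree <- function() {
  as_chronogram(ape::read.tree(text = toy_newick))
}

write_toy_newick <- function(txt = toy_newick) {
  path <- withr::local_tempfile(fileext = ".nwk",
                                .local_envir = parent.frame())
  writeLines(txt, path)
  path
}

# A small multi-gradient record set with known per-band structure.
toy_records <- function() {
  data.frame(
    gradient_id = c("G1", "G1", "G1", "G1", "G2", "G2"),
    genus = c("A", "B", "C", "A", "A", "B"),
    elevation_m = c(500, 500, 500, 1000, 250, 250),
    class = "all",
    stringsAsFactors = FALSE
  )
}

toy_profiles <- function() {
  data.frame(
    genus = c("A", "B", "C"),
    n = c(1L, 20L, 5L),
    stem_age_ma = c(40, 60, 80),
    div_rate = c(0, 0.1, 0.2),
    life_form = "unknown",
    family = NA_character_,
    stringsAsFactors = FALSE
  )
}
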
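# Shared fixture builders; everything is generated in code.

# Canonical score rows for a set of substitutions and one tool.
make_scores <- function(subs, tool, score) {
  data.frame(position = subs$position, wt = subs$wt, mut = subs$mut,
             tool = tool, score = score)
}

# A small complete panel score table where every substitution gets the same
# per-tool score triple (humdiv, humvar, provean [, sift]).
panel_scores <- function(subs, humdiv = 1, humvar = 1, provean = -10,
                         sift = NULL) {
  out <- rbind(make_scores(subs, "humdiv", humdiv),
               make_scores(subs, "humvar", humvar),
               make_scores(subs, "provean", provean))
  if (!is.null(sift)) out <- rbind(out, make_scores(subs, "sift", sift))
  out
}

# Write a tiny aligned multi-FASTA and return its path.
write_alignment_fasta <- function(rows) {
  path <- tempfile("aln-", fileext = ".fasta")
  writeLines(unlist(lapply(names(rows), function(n) c(paste0(">", n), rows[[n]]))),
             path)
  path
}

# Reference set of n_path pathogenic + n_ben benign variants over a sequence.
toy_reference <- function(sequence, n_path = 4, n_ben = 2, seed = 42) {
  subs <- enumerate_saturation(sequence)
  set.seed(seed)
  pick <- subs[sample.int(nrow(subs), n_path + n_ben), ]
  data.frame(position = pick$position, wt = pick$wt, mut = pick$mut,
             label = rep(c("pathogenic", "benign"), c(n_path, n_ben)))
}
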
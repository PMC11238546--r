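# Independent naive re-implementations used as oracles. These deliberately
# avoid the package's vectorised/grouped code paths: plain loops over rows.

naive_abundance <- function(hits, evalue_cutoff = 1e-5, marker = "rpoA") {
  samples <- unique(hits$sample_id)
  orthos <- unique(hits$subject_id)
  out <- list()
  for (s in samples) {
    raw <- stats::setNames(rep(0, length(orthos)), orthos)
    for (i in seq_len(nrow(hits))) {
      if (hits$sample_id[i] == s && hits$evalue[i] <= evalue_cutoff) {
        raw[hits$subject_id[i]] <- raw[hits$subject_id[i]] +
          hits$read_length_bp[i] / (3 * hits$subject_length_aa[i])
      }
    }
    out[[s]] <- raw[setdiff(orthos, marker)] / raw[[marker]]
  }
  out
}

random_hit_fixture <- function(n, seed, genera = NULL) {
  set.seed(seed)
  orthos <- c("desB", "desD", "entA", "rpoA")
  h <- data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    subject_id = sample(orthos, n, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3)),
    evalue = 10^stats::runif(n, -30, -3),
    bitscore = round(stats::runif(n, 40, 200), 1),
    read_length_bp = sample(50:300, n, replace = TRUE),
    subject_length_aa = sample(100:700, n, replace = TRUE),
    sample_id = sample(c("s1", "s2"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  # guarantee rpoA presence in both samples so normalization is defined
  h$subject_id[1] <- "rpoA"; h$sample_id[1] <- "s1"; h$evalue[1] <- 1e-10
  h$subject_id[2] <- "rpoA"; h$sample_id[2] <- "s2"; h$evalue[2] <- 1e-10
  if (!is.null(genera)) h$genus <- sample(genera, n, replace = TRUE)
  h
}
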
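# Shared fixtures and independent oracles for the test suite.

# Exhaustive enumeration of the bootstrap draw distribution for one ratio
# profile (temperatures x replicates matrix). Every temperature with at
# least one non-missing value contributes one uniform choice among its
# values; all choice combinations are enumerated with equal probability.
# Returns exact population moments of the abundance and stability draws.
enumerate_bootstrap <- function(ratio_matrix) {
  avail <- apply(ratio_matrix, 1, function(v) v[!is.na(v)], simplify = FALSE)
  present <- which(lengths(avail) > 0)
  grid <- as.matrix(do.call(expand.grid, avail[present]))
  low_cols <- which(present %in% c(1, 2))
  abundance <- rowMeans(grid[, low_cols, drop = FALSE])
  stability <- rowSums(grid - abundance)
  pop <- function(x) {
    mu <- mean(x)
    v <- mean((x - mu)^2)       # population variance: combos equally likely
    mu4 <- mean((x - mu)^4)
    list(mean = mu, sd = sqrt(v), var = v, mu4 = mu4)
  }
  list(abundance = pop(abundance), stability = pop(stability),
       n_combos = nrow(grid))
}

# Standard error of the sample mean / sample SD of n iid draws from the
# enumerated distribution (delta method for the SD).
se_of_mean <- function(pop, n) pop$sd / sqrt(n)
se_of_sd <- function(pop, n) {
  if (pop$var == 0) return(0)
  # exact finite-n variance of the sample variance, then delta method;
  # the asymptotic (mu4 - var^2)/n form degenerates for near-two-point
  # draw distributions (kurtosis ~ 1), which these bootstrap draws are
  var_s2 <- pop$mu4 / n - pop$var^2 * (n - 3) / (n * (n - 1))
  sqrt(max(var_s2, 0) / (4 * pop$var))
}

# Adjusted Rand index between two partitions (for cluster recovery).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maximum <- (si + sj) / 2
  (sij - expected) / (maximum - expected)
}

# Small long-format quantification fixture: `values` is a named list
# sample-key "cond.rep" -> numeric vector over temperatures.
make_quant <- function(values, protein_ids, temps = c(37, 41, 44, 47, 50,
                                                      53, 56, 59, 63, 67)) {
  rows <- lapply(names(values), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    m <- values[[key]]
    data.frame(protein_id = rep(protein_ids, each = length(temps)),
               condition = parts[1], replicate = as.integer(parts[2]),
               temperature_c = rep(temps, length(protein_ids)),
               intensity = as.vector(t(m)))
  })
  do.call(rbind, rows)
}

# Normalized-matrix fixture directly on the glog2 scale.
make_norm <- function(values, protein_ids, temps = c(37, 41, 44, 47, 50,
                                                     53, 56, 59, 63, 67)) {
  out <- make_quant(values, protein_ids, temps)
  names(out)[names(out) == "intensity"] <- "norm_value"
  out
}

# PSM-table fixture written to a temp file.
write_psm_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
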
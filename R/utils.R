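# internal helpers

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  env <- globalenv()
  if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# round half away from zero (printed limiting-dilution denominators)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# GRCh37 / hs37d5 primary chromosome lengths, used to draw IS coordinates
hs37d5_chrom_lengths <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566)

# stable genomic ordering of chromosome names (1..22, X, Y, then others)
chrom_rank <- function(chrom) {
  known <- names(hs37d5_chrom_lengths)
  r <- match(chrom, known)
  r[is.na(r)] <- length(known) + as.integer(factor(chrom[is.na(r)]))
  r
}

is_id_of <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")
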
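# Independent brute-force oracles used to validate the optimized
# implementations, plus small shared fixtures.

# O(n^2) prominence directly from the definition: walk out from the peak
# to the nearest strictly higher sample (or the edge) on each side and
# take the minimum over each stretch; prominence is peak height above the
# higher of the two base minima.
oracle_prominence <- function(x, p) {
  n <- length(x)
  higher_left <- which(x[seq_len(p - 1)] > x[p])
  lb <- if (length(higher_left)) max(higher_left) else 1L
  left_min <- min(x[lb:p])
  higher_right <- which(x[(p + 1):n] > x[p]) + p
  rb <- if (length(higher_right)) min(higher_right) else n
  right_min <- min(x[p:rb])
  x[p] - max(left_min, right_min)
}

# full reference peak selection: strict local maxima (plateaus -> first
# sample), prominence threshold, then greedy spacing by prominence
oracle_find_peaks <- function(x, min_prom, min_dist) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) oracle_prominence(x, p), numeric(1))
  cand <- cand[prom >= min_prom]
  prom <- prom[prom >= min_prom]
  kept <- integer(0)
  for (k in order(-prom, cand)) {
    if (!length(kept) || all(abs(cand[kept] - cand[k]) >= min_dist))
      kept <- c(kept, k)
  }
  sort(cand[kept])
}

# string-scan oracle for the I->E->I valid-cycle pattern over an event
# string; overlapping matches allowed (a closing I can open the next cycle)
oracle_cycle_positions <- function(labels) {
  s <- paste(ifelse(labels %in% c("inspiration_start", "I"), "I", "E"),
             collapse = "")
  n <- nchar(s)
  if (n < 3) return(integer(0))
  which(vapply(seq_len(n - 2), function(i) substr(s, i, i + 2) == "IEI",
               logical(1)))
}

# one small cached clean session shared by feature/detection tests
clean_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- simulate_subject_profiles(1, seed = 11)
      cfg <- simulation_config(seed = 11, snr_db = 30, mode = "forceful")
      cache <<- simulate_session(prof, mode = "forceful", n_cycles = 5,
                                 config = cfg)
    }
    cache
  }
})

clean_detection <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- detect_phases(clean_session())
    cache
  }
})
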
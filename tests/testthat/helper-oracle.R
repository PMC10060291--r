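# Brute-force line-of-therapy segmentation oracle.
#
# Independent of the package's incremental scan: it enumerates every
# placement of line boundaries (every subset of dispensing indices, the
# first being a mandatory line start) and keeps the placements consistent
# with the three segmentation rules — the regimen window, the new-drug
# rule with overlap carryover, and the discontinuation gap after grace.
# Exactly one placement must survive; the oracle fails loudly otherwise.

oracle_validate <- function(starts, day, drug, grace, fu_end,
                            W, G, OV) {
  n <- length(day)
  seg_start <- starts
  seg_end <- c(starts[-1] - 1L, n)
  carry <- character(0)
  carry_exp <- numeric(0)
  lots <- list()
  for (si in seq_along(seg_start)) {
    s <- seg_start[si]; e <- seg_end[si]
    start <- day[s]
    wend <- start + W
    exp <- carry_exp
    regimen <- carry
    maxexp <- if (length(exp)) max(exp) else -Inf
    for (j in s:e) {
      d <- day[j]; g <- drug[j]
      if (d <= wend) {
        regimen <- union(regimen, g)
      } else {
        if (d - maxexp >= G) return(NULL)     # forced discontinuation
        if (!(g %in% regimen)) return(NULL)   # forced new-drug boundary
      }
      old <- if (g %in% names(exp)) exp[[g]] else -Inf
      exp[[g]] <- max(old, d + grace[j])
      maxexp <- max(maxexp, exp[[g]])
    }
    if (si < length(seg_start)) {
      nj <- seg_start[si + 1L]
      d_next <- day[nj]; g_next <- drug[nj]
      if (d_next - maxexp >= G) {
        lots[[si]] <- list(start = start, end = as.integer(maxexp),
                           regimen = sort(regimen),
                           reason = "discontinuation")
        carry <- character(0); carry_exp <- numeric(0)
      } else if (!(g_next %in% regimen) && d_next > wend) {
        lots[[si]] <- list(start = start, end = d_next - 1L,
                           regimen = sort(regimen), reason = "new_drug")
        carry <- regimen[unlist(exp[regimen]) >= d_next + OV]
        carry_exp <- exp[carry]
      } else {
        return(NULL) # boundary not justified by any rule
      }
    } else {
      if (fu_end - maxexp >= G) {
        lots[[si]] <- list(start = start, end = as.integer(maxexp),
                           regimen = sort(regimen),
                           reason = "discontinuation")
      } else {
        lots[[si]] <- list(start = start,
                           end = as.integer(min(maxexp, fu_end)),
                           regimen = sort(regimen), reason = "censored")
      }
    }
  }
  lots
}

oracle_segment <- function(day, drug, grace, fu_end, W = 28L, G = 90L,
                           OV = 40L) {
  ord <- order(day, drug)
  day <- as.integer(day[ord]); drug <- drug[ord]
  grace <- as.integer(grace[ord])
  n <- length(day)
  stopifnot(n >= 1L)
  extra <- if (n > 1L) 2:n else integer(0)
  valid <- list()
  for (mask in 0:(2^length(extra) - 1L)) {
    starts <- c(1L, extra[bitwAnd(mask, 2^(seq_along(extra) - 1L)) > 0])
    res <- oracle_validate(starts, day, drug, grace, fu_end, W, G, OV)
    if (!is.null(res)) valid[[length(valid) + 1L]] <- res
  }
  if (length(valid) != 1L) {
    stop("oracle: ", length(valid), " valid boundary placements for ",
         paste(drug, day, collapse = " "), call. = FALSE)
  }
  valid[[1L]]
}

# run derive_lots on a letter/day stream and return comparable structure
engine_segment <- function(drugs, days, fu_end = 1000L,
                           params = lot_params()) {
  lots <- derive_lots(make_disp(drugs, days), make_fu(end = fu_end),
                      params = params, catalogue = abc_catalogue())
  lapply(seq_len(nrow(lots)), function(i) {
    list(start = as.integer(lots$start[i] - ORIGIN),
         end = as.integer(lots$end[i] - ORIGIN),
         regimen = sort(strsplit(lots$regimen[i], "+", fixed = TRUE)[[1]]),
         reason = lots$end_reason[i])
  })
}

# oracle on the same stream
oracle_for <- function(drugs, days, fu_end = 1000L) {
  ct <- abc_catalogue()
  grace <- ct$grace_days[match(drugs, ct$drug_name)]
  oracle_segment(days, drugs, grace, fu_end)
}

expect_oracle_equal <- function(drugs, days, fu_end = 1000L) {
  eng <- engine_segment(drugs, days, fu_end)
  ora <- oracle_for(drugs, days, fu_end)
  expect_equal(eng, ora,
               info = paste("stream:", paste(drugs, days, sep = "@",
                                             collapse = " ")))
}

# seeded random stream on a 10-day grid over 0..400
random_stream <- function(max_events = 6L, n_drugs = 3L) {
  k <- sample.int(max_events, 1L)
  days <- sort(sample(seq(0L, 400L, by = 10L), k, replace = TRUE))
  drugs <- sample(c("A", "B", "C")[seq_len(n_drugs)], k, replace = TRUE)
  list(drugs = drugs, days = days)
}
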
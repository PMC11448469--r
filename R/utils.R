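# Internal helpers shared across modules.
#
# Time convention: all instants are seconds BEFORE delivery (delivery = 0),
# so an interval [start, end) has start > end >= 0 and "chronological order"
# means decreasing start. Intervals are half-open at the delivery-side
# endpoint: the interval covers {t : end < t <= start}.

FHR_LABELS <- c("BAS", "ACC", "DEC")
UP_LABELS <- c("CON", "RIN")
GROUPS <- c("healthy", "acidosis", "HIE")

TRANSITION_PAIRS <- c("BAS>ACC", "ACC>BAS", "BAS>DEC",
                      "DEC>BAS", "ACC>DEC", "DEC>ACC")

FEATURE_NAMES <- c("t_bas_acc", "t_acc_bas", "t_bas_dec",
                   "t_dec_bas", "t_acc_dec", "t_dec_acc",
                   "d_bas", "d_acc", "d_dec", "d_con", "d_rin")

MAX_DURATION <- 43200  # 12 h monitoring cap

# Length of the intersection of interval (a_start > a_end) with
# (b_start > b_end), both in time-before-delivery coordinates. Vectorised.
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_start, b_start) - pmax(a_end, b_end))
}

# Epoch index containing an instant t > 0 (epoch k covers (k*w, (k+1)*w],
# so grid boundaries belong to the later, closer-to-delivery epoch).
epoch_of <- function(t, epoch_seconds = 1200) {
  ceiling(t / epoch_seconds) - 1L
}

# Largest-remainder apportionment of `total` into integer counts with the
# given weights; ties in remainder broken by position order.
largest_remainder <- function(weights, total) {
  quota <- weights / sum(weights) * total
  counts <- floor(quota)
  short <- total - sum(counts)
  if (short > 0) {
    ord <- order(-(quota - counts), seq_along(quota))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

# Derive reproducible child seeds from a root seed without disturbing the
# caller's RNG stream more than once. Kept below 2^31 - 1.
spawn_seeds <- function(root_seed, n) {
  old <- globalenv()$.Random.seed
  set.seed(root_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  seeds
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Merge overlapping/touching intervals given as a data.frame(start, end)
# in time-before-delivery coordinates. Returns them sorted chronologically.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  iv <- iv[order(-iv$start), , drop = FALSE]
  out_start <- iv$start[1]
  out_end <- iv$end[1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      j <- length(out_start)
      if (iv$start[i] >= out_end[j]) {
        out_end[j] <- min(out_end[j], iv$end[i])
      } else {
        out_start <- c(out_start, iv$start[i])
        out_end <- c(out_end, iv$end[i])
      }
    }
  }
  data.frame(start = out_start, end = out_end)
}
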
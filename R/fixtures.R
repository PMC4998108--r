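# Packaged stimulus sets, built in code.
#
# table3_exp2 holds the 26 delay-by-payoff choice pairs used in the main
# model contests (three 1-year periods, amounts in GBP, blanks = concealed
# zeros); the first five pairs exhibit outcome dominance. table2_exp1_*
# hold the four high/low-NPV pairs of the zero-revelation experiment, with
# zeros concealed or revealed. exp3_hidden_zero holds three smaller-sooner /
# larger-later tasks under three framing conditions. exp4_scaled is
# table3_exp2 with amounts divided by 20 and delays by 6 (months).

# Row per pair: high t1,t2,t3 then low t1,t2,t3; NA = blank slot.
.table3_rows <- function() {
  M <- rbind(
    c(800, 400, 200,  200, 400, 800),
    c(600, 400, 200,  200, 400, 600),
    c(600, 400, 200,  400, 400, 400),
    c(400, 400, 400,  200, 400, 600),
    c(800,  NA, 800,  600, 200, 800),
    c(800,  NA, 200,  200, 800,  NA),
    c(600,  NA, 200,  200, 600,  NA),
    c(400,  NA, 200,  200, 400,  NA),
    c(600,  NA, 200,   NA, 800,  NA),
    c(400,  NA, 200,   NA, 600,  NA),
    c(400,  NA, 400,   NA, 800,  NA),
    c(200,  NA, 200,   NA, 400,  NA),
    c(200, 200, 200,   NA, 600,  NA),
    c(200, 400, 200,   NA, 800,  NA),
    c(400, 200, 200,   NA, 800,  NA),
    c(400, 400, 200,  200, 800,  NA),
    c(600, 400, 200,  400, 800,  NA),
    c(800, 400, 200,  600, 800,  NA),
    c(800,  NA, 200,  400, 600,  NA),
    c(800,  NA, 200,  600, 400,  NA),
    c(600,  NA, 200,  400, 400,  NA),
    c(600, 200, 200,  400, 600,  NA),
    c(600, 200, 200,  200, 800,  NA),
    c(800,  NA, 600,  600, 400, 400),
    c(600,  NA, 600,  400, 400, 400),
    c(400,  NA, 800,  200, 400, 600))
  M
}

.grid_pairs <- function(M, delays, unit, id_prefix = "p", scale = 1) {
  lapply(seq_len(nrow(M)), function(i) {
    choice_pair(paste0(id_prefix, i),
                seq_option(M[i, 1:3] * scale, delays, unit),
                seq_option(M[i, 4:6] * scale, delays, unit))
  })
}

.table2_rows <- function(zero) {
  H <- rbind(c(300, NA, 300), c(400, NA, 200), c(400, NA, 400), c(600, NA, 200))
  L <- rbind(c(NA, 600, NA), c(NA, 600, NA), c(NA, 800, NA), c(NA, 800, NA))
  if (zero) { H[is.na(H)] <- 0; L[is.na(L)] <- 0 }
  cbind(H, L)
}

.hidden_zero_pairs <- function() {
  ss <- c(150, 300, 450); ll <- c(200, 400, 600)
  out <- list()
  for (k in 1:3) {
    # Patience is choice of the larger-later option, held in the high slot.
    out[[paste0("hz", k, "_none")]] <- choice_pair(
      paste0("hz", k, "_none"),
      seq_option(ll[k], 1), seq_option(ss[k], 0), dominance = FALSE)
    out[[paste0("hz", k, "_sooner_zero")]] <- choice_pair(
      paste0("hz", k, "_sooner_zero"),
      seq_option(c(0, ll[k]), c(0, 1)), seq_option(ss[k], 0), dominance = FALSE)
    out[[paste0("hz", k, "_later_zero")]] <- choice_pair(
      paste0("hz", k, "_later_zero"),
      seq_option(ll[k], 1), seq_option(c(ss[k], 0), c(0, 1)), dominance = FALSE)
  }
  out
}

#' Load a packaged stimulus set
#'
#' @param name One of \code{"table3_exp2"}, \code{"table2_exp1_nozero"},
#'   \code{"table2_exp1_zero"}, \code{"exp3_hidden_zero"},
#'   \code{"exp4_scaled"}.
#' @return An object of class \code{"seq_fixture"}: a named list of
#'   \code{\link{choice_pair}}s plus the set name. Byte-identical across
#'   calls; all sets are constructed in code.
#' @examples
#' length(load_fixture("table3_exp2")$pairs)  # 26
#' @export
load_fixture <- function(name) {
  valid <- c("table3_exp2", "table2_exp1_nozero", "table2_exp1_zero",
             "exp3_hidden_zero", "exp4_scaled")
  if (!name %in% valid)
    stopf("unknown fixture '%s'; valid names: %s", name,
          paste(valid, collapse = ", "))
  pairs <- switch(name,
    table3_exp2 = .grid_pairs(.table3_rows(), 1:3, "years"),
    table2_exp1_nozero = .grid_pairs(.table2_rows(FALSE), 1:3, "years", "t2n"),
    table2_exp1_zero = .grid_pairs(.table2_rows(TRUE), 1:3, "years", "t2z"),
    exp3_hidden_zero = .hidden_zero_pairs(),
    exp4_scaled = .grid_pairs(.table3_rows(), c(2, 4, 6), "months",
                              scale = 1 / 20))
  if (is.null(names(pairs)))
    names(pairs) <- vapply(pairs, function(p) p$id, "")
  structure(list(name = name, pairs = pairs), class = "seq_fixture")
}

#' @export
print.seq_fixture <- function(x, ...) {
  ndom <- sum(vapply(x$pairs, function(p) p$dominance, TRUE))
  cat(sprintf("<seq_fixture %s> %d pairs (%d with dominance relations)\n",
              x$name, length(x$pairs), ndom))
  invisible(x)
}

#' Write choice pairs to a stimulus CSV
#'
#' One row per grid cell with columns \code{pair_id}, \code{option}
#' (\code{H}/\code{L}), \code{period}, \code{delay}, \code{delay_unit},
#' \code{amount}, \code{status}.
#'
#' @param x A \code{seq_fixture} or list of \code{\link{choice_pair}}s.
#' @param path Output file path.
#' @export
write_stimuli <- function(x, path) {
  pairs <- if (inherits(x, "seq_fixture")) x$pairs else x
  rows <- do.call(rbind, lapply(pairs, function(p) {
    one <- function(opt, lab) data.frame(
      pair_id = p$id, option = lab, period = seq_along(opt$delay),
      delay = opt$delay, delay_unit = opt$unit, amount = opt$amount,
      status = opt$status, stringsAsFactors = FALSE)
    rbind(one(p$high, "H"), one(p$low, "L"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read choice pairs from a stimulus CSV
#'
#' Inverse of \code{\link{write_stimuli}}; dominance flags are recomputed for
#' shared-grid pairs.
#'
#' @param path CSV file written by \code{\link{write_stimuli}}.
#' @return A list of \code{\link{choice_pair}}s named by id.
#' @export
read_stimuli <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$pair_id)
  pairs <- lapply(ids, function(id) {
    di <- d[d$pair_id == id, ]
    build <- function(lab) {
      o <- di[di$option == lab, ]
      o <- o[order(o$period), ]
      amt <- ifelse(o$status == "blank", NA, o$amount)
      seq_option(amt, o$delay, o$delay_unit[1])
    }
    h <- build("H"); l <- build("L")
    dom <- if (identical(h$delay, l$delay)) NULL else FALSE
    choice_pair(id, h, l, dominance = dom)
  })
  names(pairs) <- ids
  pairs
}
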
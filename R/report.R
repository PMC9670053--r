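#' @title Total-cost summary, shares and currency conversion
#' @description
#' Combines the direct and indirect reports into the employer's total cost,
#' computes the percentage share of each component, and converts ETB figures
#' to USD at a single, explicitly stated exchange rate. One rate per report:
#' mixed implicit rates make published USD columns internally inconsistent,
#' so every converted figure here uses the same rate.
#' @name cost-summary
NULL

#' Exchange rate
#'
#' @param etb_per_usd ETB per 1 USD; default 44.32, the 2021 average annual
#'   ETB/USD rate of the Commercial Bank of Ethiopia.
#' @return An `exchange_rate` object.
#' @export
exchange_rate <- function(etb_per_usd = 44.32) {
  check_number(etb_per_usd, "etb_per_usd", 0, strict_lower = TRUE)
  structure(list(etb_per_usd = etb_per_usd), class = "exchange_rate")
}

#' Total cost
#'
#' Sum of direct and indirect costs; both must be non-negative.
#'
#' @param direct,indirect Costs in ETB.
#' @return Total cost (ETB).
#' @export
total_cost <- function(direct, indirect) {
  check_number(direct, "direct", 0)
  check_number(indirect, "indirect", 0)
  direct + indirect
}

#' Percentage shares of direct and indirect cost
#'
#' @param direct,indirect Non-negative costs (ETB) with a positive sum.
#' @return Named numeric `c(direct, indirect)` in percent, half-up to two
#'   decimals.
#' @examples
#' cost_shares(7711584, 14876051.32) # 34.14 / 65.86
#' @export
cost_shares <- function(direct, indirect) {
  check_number(direct, "direct", 0)
  check_number(indirect, "indirect", 0)
  tot <- direct + indirect
  if (tot <= 0) stop("direct + indirect must be positive", call. = FALSE)
  round_half_up(c(direct = 100 * direct / tot,
                  indirect = 100 * indirect / tot), 2)
}

#' Convert ETB to USD
#'
#' @param amount Amount in ETB (may be a vector).
#' @param rate An [exchange_rate()].
#' @return USD amounts, half-up to cents.
#' @examples
#' to_usd(7711584, exchange_rate(44.32)) # 173997.83
#' @export
to_usd <- function(amount, rate = exchange_rate()) {
  stopifnot(inherits(rate, "exchange_rate"), is.numeric(amount))
  round_half_up(amount / rate$etb_per_usd, 2)
}

#' Build the total-cost summary
#'
#' @param direct_report A [direct_cost_report()].
#' @param indirect_report An [indirect_cost_report()].
#' @param rate An [exchange_rate()]; the single rate applied to every USD
#'   figure.
#' @return A `cost_summary` list: `direct`, `indirect`, `total` (ETB, full
#'   precision); `direct_share`, `indirect_share` (percent); `usd` (named
#'   vector: direct, indirect, total); `rate`.
#' @export
build_summary <- function(direct_report, indirect_report,
                          rate = exchange_rate()) {
  stopifnot(inherits(direct_report, "direct_cost_report"),
            inherits(indirect_report, "indirect_cost_report"),
            inherits(rate, "exchange_rate"))
  d <- direct_report$total_direct
  i <- indirect_report$total_indirect
  shares <- cost_shares(d, i)
  structure(list(
    direct = d,
    indirect = i,
    total = total_cost(d, i),
    direct_share = unname(shares["direct"]),
    indirect_share = unname(shares["indirect"]),
    usd = to_usd(c(direct = d, indirect = i, total = d + i), rate),
    rate = rate,
    direct_report = direct_report,
    indirect_report = indirect_report
  ), class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("Employer cost of occupational injury (ETB; USD at %.2f ETB/USD)\n",
              x$rate$etb_per_usd))
  row <- function(lab, etb, usd, share) {
    cat(sprintf("  %-9s %16.2f ETB  (%12.2f $)  %6.2f%%\n",
                lab, round_half_up(etb), usd, share))
  }
  row("direct", x$direct, x$usd[["direct"]], x$direct_share)
  row("indirect", x$indirect, x$usd[["indirect"]], x$indirect_share)
  row("total", x$total, x$usd[["total"]], 100)
  invisible(x)
}

#' Write a cost summary to disk
#'
#' JSON is the canonical machine-readable format (full precision); TSV is a
#' two-decimal display rendering.
#'
#' @param summary A [build_summary()] result.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, format = c("json", "tsv")) {
  stopifnot(inherits(summary, "cost_summary"))
  format <- match.arg(format)
  if (format == "json") {
    out <- list(
      etb = list(direct = summary$direct, indirect = summary$indirect,
                 total = summary$total),
      shares_percent = list(direct = summary$direct_share,
                            indirect = summary$indirect_share),
      usd = as.list(summary$usd),
      etb_per_usd = summary$rate$etb_per_usd
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      component = c("direct", "indirect", "total"),
      etb = sprintf("%.2f", round_half_up(
        c(summary$direct, summary$indirect, summary$total))),
      usd = sprintf("%.2f", summary$usd),
      share_percent = sprintf("%.2f", c(summary$direct_share,
                                        summary$indirect_share, 100)))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
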
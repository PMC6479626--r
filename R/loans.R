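#' Level monthly repayment for a Skyloo loan
#'
#' Annuity-due payment amortizing `principal` over `term` months at
#' monthly rate `rate`, with payments at the start of each month:
#' `P * r / ((1 + r) * (1 - (1 + r)^-n))`, optionally rounded to a cash
#' granularity. At `rate = 0` this is simply `principal / term`.
#'
#' For the MK200,000 Skyloo loan at 1% per month over two years this gives
#' MK9321.5, i.e. MK9320 at MK10 granularity -- the repayment historically
#' charged by the loan scheme the business model emulates.
#'
#' @param principal loan principal, MK.
#' @param rate monthly interest rate; >= 0.
#' @param term number of monthly payments; >= 1.
#' @param rounding cash granularity in MK (e.g. 10 rounds to the nearest
#'   MK10); `NULL` for no rounding.
#' @return Monthly payment, MK.
#' @examples
#' required_payment(200000, 0.01, 24, rounding = 10)  # 9320
#' @export
required_payment <- function(principal, rate, term, rounding = NULL) {
  check_pos(principal, "principal")
  check_pos(rate, "rate", strict = FALSE)
  term <- check_count(term, "term")
  pay <- if (rate == 0) principal / term
         else principal * rate / ((1 + rate) * (1 - (1 + rate)^(-term)))
  if (!is.null(rounding)) pay <- round(pay / rounding) * rounding
  pay
}

#' Amortization schedule implied by a fixed payment
#'
#' Iterates the balance recursion `B <- B * (1 + rate) - payment` until the
#' balance reaches zero; the final payment is truncated to the exact payoff
#' amount. Used to answer "how long does the MK7000 repayment scheme take
#' to clear a MK200,000 loan?" (34 months).
#'
#' @param principal loan principal, MK.
#' @param rate monthly interest rate.
#' @param payment fixed monthly payment, MK; must exceed
#'   `principal * rate` or the loan never amortizes.
#' @return List with `term` (number of payments) and `final_payment` (MK,
#'   `<= payment`).
#' @examples
#' loan_schedule(200000, 0.01, 7000)$term  # 34
#' @export
loan_schedule <- function(principal, rate, payment) {
  check_pos(principal, "principal")
  check_pos(rate, "rate", strict = FALSE)
  check_pos(payment, "payment")
  if (payment <= principal * rate)
    stop("payment does not exceed monthly interest: loan never amortizes",
         call. = FALSE)
  balance <- principal
  term <- 0L
  repeat {
    balance <- balance * (1 + rate)
    term <- term + 1L
    if (balance <= payment) {
      final <- balance
      break
    }
    balance <- balance - payment
  }
  list(term = term, final_payment = final)
}
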
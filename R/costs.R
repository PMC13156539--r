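#' Present value of the fixed program costs
#'
#' Amortizes the one-time development costs plus an annual recurring fee
#' over the program's operational horizon as an annuity-due (the first
#' annual payment falls at the start of year 1 and is undiscounted):
#' `PV = one_time + sum_{t=0}^{Y-1} annual / (1 + r)^t`.
#'
#' @param one_time one-time costs (US$), e.g. app development plus video
#'   production.
#' @param annual recurring cost per year (US$), e.g. therapist
#'   consultation fees.
#' @param horizon_years operational horizon in years (>= 1).
#' @param discount_rate annual discount rate (fraction, >= 0).
#' @return Total present value in US$.
#' @examples
#' amortize_fixed_costs(15761.19, 4298.51, 5, 0.03)  # ~36,037.68
#' @export
amortize_fixed_costs <- function(one_time, annual, horizon_years = 5,
                                 discount_rate = 0.03) {
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  if (any(c(one_time, annual) < 0))
    stop("monetary inputs must be >= 0", call. = FALSE)
  one_time + sum(annual / (1 + discount_rate)^(0:(horizon_years - 1)))
}

#' Per-participant fixed-cost share for one period
#'
#' Divides the amortized present value evenly over
#' `horizon_years * periods_per_year` periods and `n_participants`
#' participants per period.
#'
#' @param total_pv amortized present value (US$).
#' @param horizon_years program horizon in years.
#' @param periods_per_year accounting periods per year (2 for 6-month
#'   periods).
#' @param n_participants participants served per period.
#' @return US$ per participant per period.
#' @examples
#' per_participant_period_share(36037.68, 5, 2, 96)  # ~37.54
#' @export
per_participant_period_share <- function(total_pv, horizon_years,
                                         periods_per_year, n_participants) {
  denom <- horizon_years * periods_per_year * n_participants
  if (!is.finite(denom) || denom <= 0)
    stop("horizon, periods and participants must all be positive",
         call. = FALSE)
  total_pv / denom
}

#' Average daily labor income
#'
#' @param annual_income per-capita annual income (US$).
#' @param working_days_per_year working days per year (default 260).
#' @return US$ per working day.
#' @examples
#' daily_income(10606.27)  # ~40.79
#' @export
daily_income <- function(annual_income, working_days_per_year = 260) {
  if (working_days_per_year <= 0)
    stop("working_days_per_year must be > 0", call. = FALSE)
  if (annual_income < 0) stop("annual_income must be >= 0", call. = FALSE)
  annual_income / working_days_per_year
}

#' Human-capital indirect cost
#'
#' Values time lost to medical care at the average daily income:
#' inpatient days count in full, clinic visits as half a day each.
#'
#' @param inpatient_days inpatient days over the horizon (>= 0).
#' @param clinic_visits number of clinic visits (>= 0).
#' @param income_per_day average daily labor income (US$).
#' @return US$ of lost productivity.
#' @examples
#' indirect_cost(0, 4, 40.80)  # 81.60
#' @export
indirect_cost <- function(inpatient_days, clinic_visits, income_per_day) {
  if (any(inpatient_days < 0) || any(clinic_visits < 0))
    stop("counts must be >= 0", call. = FALSE)
  (inpatient_days + 0.5 * clinic_visits) * income_per_day
}

#' Total societal cost
#'
#' @param direct direct medical costs (US$).
#' @param indirect indirect (productivity) costs (US$).
#' @param fixed_share per-participant fixed-cost share (US$); 0 in the
#'   control arm.
#' @return The exact sum in US$.
#' @examples
#' total_cost(9113.58, 144.33, 37.54)  # 9295.45
#' @export
total_cost <- function(direct, indirect, fixed_share) {
  if (any(c(direct, indirect, fixed_share) < 0))
    stop("cost components must be >= 0", call. = FALSE)
  direct + indirect + fixed_share
}

#' Convert an amount to US dollars
#'
#' @param amount amount in local currency.
#' @param rate exchange rate expressed as local currency per USD (> 0).
#' @return US$ amount (`amount / rate`).
#' @export
convert_currency <- function(amount, rate) {
  if (any(rate <= 0)) stop("exchange rate must be > 0", call. = FALSE)
  amount / rate
}

#' Per-participant societal cost breakdown
#'
#' Builds the fixed / direct / indirect / total cost decomposition for
#' every participant in a panel: the fixed-cost share is the amortized
#' per-participant period share for the intervention arm and 0 for the
#' control arm; indirect costs apply the human-capital approach to the
#' recorded inpatient days and clinic visits.
#'
#' @param panel an `outcome_panel`.
#' @param cost_params list as produced by [default_cost_params()].
#' @return Data frame, one row per participant: `participant_id`, `arm`,
#'   `endocrine_therapy`, `fixed_share`, `direct`, `indirect`, `total`.
#' @export
cost_breakdown <- function(panel, cost_params = default_cost_params()) {
  pt <- participant_table(panel)
  fx <- cost_params$fixed
  pv <- amortize_fixed_costs(fx$one_time, fx$annual, fx$horizon_years,
                             fx$discount_rate)
  share <- per_participant_period_share(pv, fx$horizon_years,
                                        fx$periods_per_year,
                                        fx$n_program_participants)
  inc <- daily_income(cost_params$annual_income,
                      cost_params$working_days_per_year)
  out <- data.frame(
    participant_id = pt$participant_id, arm = pt$arm,
    endocrine_therapy = pt$endocrine_therapy,
    fixed_share = ifelse(pt$arm == "intervention", share, 0),
    direct = pt$direct_cost,
    indirect = indirect_cost(pt$inpatient_days, pt$clinic_visits, inc),
    stringsAsFactors = FALSE)
  out$total <- total_cost(out$direct, out$indirect, out$fixed_share)
  out
}
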
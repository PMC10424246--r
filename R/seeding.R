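#' Droplet-printing seeding plan
#'
#' In pass-based droplet printing, one "pass" deposits one layer of
#' cell-laden medium over the insert; the delivered cell dose scales
#' linearly with the pass count. Defaults encode the study design this
#' package quantifies: 2200 cells per insert per pass, 6.5 mm inserts
#' covered by a 7 mm printed spot, ~0.2 min per pass.
#'
#' @param passes number of printed passes (integer >= 0).
#' @param cells_per_pass cells deposited per insert per pass.
#' @param insert_diameter insert diameter (mm).
#' @param printed_spot_diameter printed spot diameter (mm); must cover the
#'   insert.
#' @param est_time_per_pass estimated printing time per pass (min).
#' @return an object of class `print_plan`.
#' @export
print_plan <- function(passes, cells_per_pass = 2200, insert_diameter = 6.5,
                       printed_spot_diameter = 7, est_time_per_pass = 0.2) {
  if (!is.numeric(passes) || length(passes) != 1L || passes < 0 ||
      passes != round(passes))
    stop("'passes' must be a single non-negative integer")
  .check_positive(cells_per_pass = cells_per_pass,
                  insert_diameter = insert_diameter,
                  printed_spot_diameter = printed_spot_diameter,
                  est_time_per_pass = est_time_per_pass)
  if (printed_spot_diameter < insert_diameter)
    stop("printed spot must cover the insert ",
         "(printed_spot_diameter >= insert_diameter)")
  structure(list(passes = as.integer(passes),
                 cells_per_pass = cells_per_pass,
                 insert_diameter = insert_diameter,
                 printed_spot_diameter = printed_spot_diameter,
                 est_time_per_pass = est_time_per_pass),
            class = "print_plan")
}

#' Cell dose delivered per insert by a print plan
#' @param plan a [print_plan()].
#' @return total cells per insert (passes x cells per pass).
#' @examples
#' cells_per_insert(print_plan(50))  # 1.1e5
#' @export
cells_per_insert <- function(plan) {
  if (!inherits(plan, "print_plan")) stop("'plan' must be a print_plan")
  plan$passes * plan$cells_per_pass
}

#' Planning summary for a print plan
#'
#' @param plan a [print_plan()].
#' @param manual_reference manually seeded cell dose used as the
#'   benchmark (cells/insert).
#' @return list with `cells`, `est_print_time` (min) and
#'   `fraction_of_manual` (printed dose / manual dose).
#' @examples
#' plan_summary(print_plan(10))$fraction_of_manual  # 0.1
#' @export
plan_summary <- function(plan, manual_reference = 2.2e5) {
  if (!inherits(plan, "print_plan")) stop("'plan' must be a print_plan")
  .check_positive(manual_reference = manual_reference)
  cells <- cells_per_insert(plan)
  list(cells = cells,
       est_print_time = plan$passes * plan$est_time_per_pass,
       fraction_of_manual = cells / manual_reference)
}

#' Dosing table across pass counts
#' @param passes vector of pass counts.
#' @param ... passed to [print_plan()].
#' @param manual_reference manual-seeding benchmark dose.
#' @return data.frame with `passes`, `cells`, `est_print_time_min`,
#'   `fraction_of_manual`.
#' @export
dosing_table <- function(passes = c(10, 20, 30, 40, 50), ...,
                         manual_reference = 2.2e5) {
  rows <- lapply(passes, function(p) {
    s <- plan_summary(print_plan(p, ...), manual_reference)
    data.frame(passes = p, cells = s$cells,
               est_print_time_min = s$est_print_time,
               fraction_of_manual = s$fraction_of_manual)
  })
  do.call(rbind, rows)
}
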
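#' Read a descriptor table CSV
#'
#' Dialect: header
#' `compound_id,mw,tpsa,hbd,logp,logd74,pka_basic[,dg_hyd]`.
#'
#' @param path CSV file path.
#' @return Data frame with the descriptor columns.
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "mw", "tpsa", "hbd", "logp", "logd74", "pka_basic")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("read_descriptor_table: missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' Write a descriptor table CSV in the package dialect
#'
#' @param sets List of `gt_descriptor_set` objects (or a data frame passed
#'   through unchanged).
#' @param path Output CSV path.
#' @export
write_descriptor_table <- function(sets, path) {
  df <- if (is.data.frame(sets)) sets else do.call(rbind, lapply(sets, function(d)
    data.frame(compound_id = d$compound_id, mw = d$mw, tpsa = d$tpsa,
               hbd = d$hbd, logp = d$logp, logd74 = d$logd74,
               pka_basic = d$pka_basic, dg_hyd = d$dg_hyd)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy GTT/ITT glycemia table
#'
#' Dialect: `animal,group,time_min,glycemia_mg_dl`.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_glycemia_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal", "group", "time_min", "glycemia_mg_dl")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("read_glycemia_table: missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$glycemia_mg_dl <= 0)) stop("read_glycemia_table: glycemia must be > 0")
  if (any(df$time_min < 0)) stop("read_glycemia_table: times must be >= 0")
  df
}

#' Read grid boxes from YAML
#'
#' Expected structure: a mapping of target id to `center: [x, y, z]` and
#' `dims: [dx, dy, dz]`.
#'
#' @param path YAML file path.
#' @return Named list of `gt_grid_box` objects.
#' @export
read_grid_boxes <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(stats::setNames(names(y), names(y)), function(id)
    grid_box(unlist(y[[id]]$center), unlist(y[[id]]$dims), target = id))
}
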
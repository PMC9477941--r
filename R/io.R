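# Plain-text, self-describing file formats.  No standard bioformat exists for
# 1D haemodynamic networks, so the network file is a sectioned text format
# with unit suffixes in the headers; waveforms and traces are TSV.  Writing is
# canonical: write -> read -> write is byte-identical.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Write a network description file
#'
#' Canonical sectioned text format: blood properties, scheme, one row per
#' vessel / junction / terminal / stenosis, the inlet block and the inlet
#' waveform sampled inline.  Units are SI and named in the headers.
#'
#' @param network an [arterial_network()].
#' @param path output file path.
#' @param waveform_samples number of waveform samples written when the inlet
#'   waveform is an analytic closure.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, waveform_samples = 256L) {
  v1 <- network$vessels[[1]]
  out <- c("# cardiowave network v1",
           "[blood]",
           paste("rho_kg_m3", .fmt_num(v1$rho)),
           paste("mu_Pa_s", .fmt_num(v1$mu)),
           paste("zeta", .fmt_num(v1$zeta)),
           paste("P_ext_Pa", .fmt_num(v1$P_ext)),
           "[scheme]",
           paste("order", network$scheme$order),
           paste("limiter", network$scheme$limiter),
           paste("total_pressure", as.integer(network$scheme$total_pressure)),
           "[vessels]",
           "# id length_m n_elem A_in_m2 A_out_m2 E_Pa h_m phi_Pa_s")
  for (i in seq_along(network$vessels)) {
    v <- network$vessels[[i]]
    out <- c(out, paste(i, .fmt_num(v$length), v$n_elem,
                        .fmt_num(v$A0_in), .fmt_num(v$A0_out),
                        .fmt_num(v$E[1]), .fmt_num(v$h[1]),
                        .fmt_num(v$phi_w[1])))
  }
  out <- c(out, "[junctions]", "# parent children...")
  for (j in network$junctions)
    out <- c(out, paste(c(j$parent, j$children), collapse = " "))
  out <- c(out, "[terminals]", "# vessel Z_Pa_s_m3 R_Pa_s_m3 C_m3_Pa P_out_Pa")
  for (t in network$terminals)
    out <- c(out, paste(t$vessel, .fmt_num(t$Z), .fmt_num(t$R),
                        .fmt_num(t$C), .fmt_num(t$P_out)))
  out <- c(out, "[stenoses]", "# vessel pos_frac area_ratio Ls_m Kv Kt Ku")
  for (s in network$stenoses)
    out <- c(out, paste(s$vessel, .fmt_num(s$pos_frac), .fmt_num(s$area_ratio),
                        .fmt_num(s$Ls), .fmt_num(s$Kv), .fmt_num(s$Kt),
                        .fmt_num(s$Ku)))
  bc <- network$inlet$waveform
  out <- c(out, "[inlet]",
           paste("vessel", network$inlet$vessel),
           paste("kind", if (is.null(bc)) "none" else bc$kind))
  if (!is.null(bc)) {
    out <- c(out, paste("period_s", .fmt_num(bc$period)), "[waveform]",
             "# t_s value")
    tab <- if (!is.null(bc$table)) bc$table else .bc_table(bc, waveform_samples)
    out <- c(out, paste(.fmt_num(tab$t), .fmt_num(tab$value)))
  }
  writeLines(out, path)
  invisible(path)
}

.split_sections <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- cumsum(startsWith(lines, "["))
  split(lines, sec)
}

.kv <- function(lines) {
  kv <- strsplit(lines[-1], "\\s+")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = " ")),
                  vapply(kv, `[[`, character(1), 1))
}

#' Read a network description file
#'
#' @param path file written by [write_network()].
#' @return An [arterial_network()].
#' @export
read_network <- function(path) {
  secs <- .split_sections(readLines(path))
  names(secs) <- vapply(secs, function(s) gsub("\\[|\\]", "", s[1]), character(1))
  need <- c("blood", "scheme", "vessels", "junctions", "terminals",
            "stenoses", "inlet")
  if (!all(need %in% names(secs)))
    stop("bad network file: missing section(s) ",
         paste(setdiff(need, names(secs)), collapse = ", "))
  blood <- .kv(secs$blood)
  scheme <- .kv(secs$scheme)
  rows <- function(s) lapply(s[-1], function(l) strsplit(l, "\\s+")[[1]])
  vessels <- lapply(rows(secs$vessels), function(r) {
    r <- as.numeric(r)
    vessel_segment(as.integer(r[1]), r[2], as.integer(r[3]), r[4], r[5],
                   E = r[6], h = r[7], phi_w = r[8],
                   rho = as.numeric(blood$rho_kg_m3),
                   mu = as.numeric(blood$mu_Pa_s),
                   zeta = as.numeric(blood$zeta),
                   P_ext = as.numeric(blood$P_ext_Pa))
  })
  junctions <- lapply(rows(secs$junctions), function(r) {
    r <- as.integer(r)
    list(parent = r[1], children = r[-1])
  })
  terminals <- lapply(rows(secs$terminals), function(r) {
    r <- as.numeric(r)
    windkessel_terminal(r[2], r[3], r[4], r[5], vessel = as.integer(r[1]))
  })
  stenoses <- lapply(rows(secs$stenoses), function(r) {
    r <- as.numeric(r)
    vi <- as.integer(r[1])
    nel <- vessels[[vi]]$n_elem
    iface <- min(max(1L, as.integer(round(r[2] * nel))), nel - 1L)
    list(vessel = vi, pos_frac = r[2], iface = iface, area_ratio = r[3],
         Ls = r[4], Kv = r[5], Kt = r[6], Ku = r[7], q_state = 0)
  })
  inl <- .kv(secs$inlet)
  waveform <- NULL
  if (!identical(inl$kind, "none")) {
    if (!"waveform" %in% names(secs)) stop("bad network file: waveform missing")
    wtab <- do.call(rbind, lapply(rows(secs$waveform), as.numeric))
    waveform <- inflow_bc(inl$kind, period = as.numeric(inl$period_s),
                          table = data.frame(t = wtab[, 1], value = wtab[, 2]))
  }
  arterial_network(vessels, junctions, terminals, stenoses,
                   inlet = list(vessel = as.integer(inl$vessel),
                                kind = inl$kind, waveform = waveform),
                   scheme = list(order = as.integer(scheme$order),
                                 limiter = scheme$limiter,
                                 total_pressure = scheme$total_pressure == "1"))
}

#' Write / read a waveform or trace table as TSV
#'
#' @param x data frame.
#' @param path file path.
#' @return `path` / the data frame.
#' @export
write_waveform <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

# ---------------------------------------------------------------------------
# Run configuration (YAML)

.config_schema <- list(
  network = c("file", "fixture", "args"),
  scheme = c("dt1D_s", "dt3D_s", "order", "limiter"),
  coupling = c("k_max", "tol_abs", "V_scale_m3", "fd_eps_Pa", "hysteresis_Pa"),
  cavity = c("type", "period_s", "preload_Pa", "V_rest_m3", "E_min_Pa_m3",
             "E_max_Pa_m3", "R_i_m", "R_o_m", "C_guc_Pa", "b_f", "b_t",
             "b_fs", "kappa_Pa", "S_peak_Pa", "t_dur_s", "tau_c0_s",
             "tau_r_s", "ld", "ld_up_s", "lambda0", "t_emd_s", "t_a_s"),
  valve = c("B", "L_in"),
  run = c("init_cycles", "beats", "output_dir", "seed")
)

#' Read and validate a run configuration file
#'
#' YAML file with sections `network`, `scheme`, `coupling`, `cavity`, `valve`,
#' `run`.  Unknown sections or keys are rejected.  Units are SI and carried in
#' the key names.
#'
#' @param path YAML file path.
#' @return Validated configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(.config_schema))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (s in names(cfg)) {
    bk <- setdiff(names(cfg[[s]]), .config_schema[[s]])
    if (length(bk))
      stop(sprintf("unknown key(s) in [%s]: %s", s, paste(bk, collapse = ", ")))
  }
  defaults <- list(
    scheme = list(dt1D_s = 1e-4, dt3D_s = 1e-3, order = 2L, limiter = "minmod"),
    coupling = list(k_max = 10L, tol_abs = 1e-6, V_scale_m3 = 1e-6,
                    fd_eps_Pa = 10, hysteresis_Pa = 1),
    cavity = list(type = "sphere", period_s = 1.231, preload_Pa = 1333.22),
    valve = list(B = 4.5e9, L_in = 5e4),
    run = list(init_cycles = 20L, beats = 3L, output_dir = ".", seed = 1L)
  )
  for (s in names(defaults)) {
    cfg[[s]] <- utils::modifyList(defaults[[s]], if (is.null(cfg[[s]])) list() else cfg[[s]])
  }
  cfg
}
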
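# Gaussian basis-set data (standard published exponents/contractions) for the
# elements covered by the fixture molecules.  Shells are stored per element as
# list(l, exps, coefs); SP shells are split into separate s and p entries.

.sto3g_coreS <- c(0.1543289673, 0.5353281423, 0.4446345422)
.sto3g_valS <- c(-0.09996722919, 0.3995128261, 0.7001154689)
.sto3g_valP <- c(0.1559162750, 0.6076837186, 0.3919573931)

.basis_library <- list(
  "sto-3g" = list(
    H = list(list(l = 0L, exps = c(3.425250914, 0.6239137298, 0.1688554040),
                  coefs = .sto3g_coreS)),
    C = list(
      list(l = 0L, exps = c(71.61683735, 13.04509632, 3.530512160),
           coefs = .sto3g_coreS),
      list(l = 0L, exps = c(2.941249355, 0.6834830964, 0.2222899159),
           coefs = .sto3g_valS),
      list(l = 1L, exps = c(2.941249355, 0.6834830964, 0.2222899159),
           coefs = .sto3g_valP)),
    N = list(
      list(l = 0L, exps = c(99.10616896, 18.05231239, 4.885660238),
           coefs = .sto3g_coreS),
      list(l = 0L, exps = c(3.780455879, 0.8784966449, 0.2857143744),
           coefs = .sto3g_valS),
      list(l = 1L, exps = c(3.780455879, 0.8784966449, 0.2857143744),
           coefs = .sto3g_valP)),
    O = list(
      list(l = 0L, exps = c(130.7093214, 23.80886605, 6.443608313),
           coefs = .sto3g_coreS),
      list(l = 0L, exps = c(5.033151319, 1.169596125, 0.3803889600),
           coefs = .sto3g_valS),
      list(l = 1L, exps = c(5.033151319, 1.169596125, 0.3803889600),
           coefs = .sto3g_valP))
  ),
  "6-31g" = list(
    H = list(
      list(l = 0L, exps = c(18.73113696, 2.825394365, 0.6401216923),
           coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
      list(l = 0L, exps = 0.1612777588, coefs = 1.0)),
    C = list(
      list(l = 0L,
           exps = c(3047.524880, 457.3695180, 103.9486850, 29.21015530,
                    9.286662960, 3.163926960),
           coefs = c(0.001834737132, 0.01403732281, 0.06884262226,
                     0.2321844432, 0.4679413484, 0.3623119853)),
      list(l = 0L, exps = c(7.868272350, 1.881288540, 0.5442492580),
           coefs = c(-0.1193324198, -0.1608541517, 1.143456438)),
      list(l = 1L, exps = c(7.868272350, 1.881288540, 0.5442492580),
           coefs = c(0.06899906659, 0.3164239610, 0.7443082909)),
      list(l = 0L, exps = 0.1687144782, coefs = 1.0),
      list(l = 1L, exps = 0.1687144782, coefs = 1.0)),
    N = list(
      list(l = 0L,
           exps = c(4173.511460, 627.4579110, 142.9020930, 42.32335890,
                    14.18905540, 4.543544220),
           coefs = c(0.00183477216, 0.013994627, 0.0685866218, 0.232240873,
                     0.469069948, 0.360455199)),
      list(l = 0L, exps = c(11.62636186, 2.716279807, 0.7722183966),
           coefs = c(-0.1149611817, -0.1691174786, 1.145851947)),
      list(l = 1L, exps = c(11.62636186, 2.716279807, 0.7722183966),
           coefs = c(0.06757974388, 0.3239072959, 0.7408951398)),
      list(l = 0L, exps = 0.2120314975, coefs = 1.0),
      list(l = 1L, exps = 0.2120314975, coefs = 1.0)),
    O = list(
      list(l = 0L,
           exps = c(5484.671660, 825.2349460, 188.0469580, 52.96450000,
                    16.89757040, 5.799635340),
           coefs = c(0.001831074430, 0.01395017220, 0.06844507810,
                     0.2327143360, 0.4701928980, 0.3585208530)),
      list(l = 0L, exps = c(15.53961625, 3.599933586, 1.013761750),
           coefs = c(-0.1107775495, -0.1480262627, 1.130767015)),
      list(l = 1L, exps = c(15.53961625, 3.599933586, 1.013761750),
           coefs = c(0.07087426823, 0.3397528391, 0.7271585773)),
      list(l = 0L, exps = 0.2700058226, coefs = 1.0),
      list(l = 1L, exps = 0.2700058226, coefs = 1.0))
  )
)

#' Names of the built-in primary basis sets
#' @return character vector of basis-set identifiers
#' @export
availableBases <- function() names(.basis_library)
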
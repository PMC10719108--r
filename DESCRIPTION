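Package: microxtal
Title: Serial X-Ray and Electron Microcrystallography of Small Organic Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing serial femtosecond X-ray crystallography (SX)
    and 3D electron diffraction (MicroED) of small organic microcrystals.
    Implements atomic X-ray and electron scattering factors with partial-charge
    interpolation and the Mott-Bethe conversion, direct-summation structure
    factors for P1, P-1 and Pbca with systematic absences, Fourier map
    synthesis with hydrogen-omit difference maps, the 1s hydrogen
    electron-density to Coulomb-potential theory with thermally smeared bond
    profiles, hydrogen peak statistics in sigma-scaled maps, shell-resolved
    R factors with a partial-charge grid search, Monte-Carlo merging of still
    frames with half-set statistics (R_split, R_merge, CC_1/2, completeness,
    multiplicity), and seeded synthetic-data generators that make every stage
    testable without measured data.  Reflections are read and written in SHELX
    HKLF-4 format and structures as minimal CIF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
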
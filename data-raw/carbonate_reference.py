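"""Independent reference solver for the seawater CO2 system.

Written separately from the R implementation as a cross-check oracle:
instead of the direct TA->carbonate-alkalinity algebra, it root-solves the
full proton condition for DIC with scipy, then derives pCO2 from the
speciated DIC. Constants: Lueker et al. (2000) K1/K2 (total scale),
Weiss (1974) K0, Dickson (1990) KB, DOE handbook KW (total scale),
Uppstrom (1974) total boron.

Regenerates tests/testthat/fixtures/carbonate-reference-grid.csv:

    python data-raw/carbonate_reference.py
"""
import itertools
import math

from scipy.optimize import brentq


def constants(temp_c, sal):
    tk = temp_c + 273.15
    s = sal
    k0 = math.exp(
        93.4517 * (100.0 / tk)
        - 60.2409
        + 23.3585 * math.log(tk / 100.0)
        + s * (0.023517 - 0.023656 * (tk / 100.0)
               + 0.0047036 * (tk / 100.0) ** 2)
    )
    k1 = 10.0 ** -(3633.86 / tk - 61.2172 + 9.6777 * math.log(tk)
                   - 0.011555 * s + 0.0001152 * s * s)
    k2 = 10.0 ** -(471.78 / tk + 25.929 - 3.16967 * math.log(tk)
                   - 0.01781 * s + 0.0001122 * s * s)
    kb = math.exp(
        (-8966.90 - 2890.53 * s ** 0.5 - 77.942 * s
         + 1.728 * s ** 1.5 - 0.0996 * s * s) / tk
        + 148.0248 + 137.1942 * s ** 0.5 + 1.62142 * s
        + (-24.4344 - 25.085 * s ** 0.5 - 0.2474 * s) * math.log(tk)
        + 0.053105 * s ** 0.5 * tk
    )
    kw = math.exp(
        148.96502 - 13847.26 / tk - 23.6521 * math.log(tk)
        + (118.67 / tk - 5.977 + 1.0495 * math.log(tk)) * s ** 0.5
        - 0.01615 * s
    )
    bt = 0.0004157 * s / 35.0
    return k0, k1, k2, kb, kw, bt


def ta_from_dic_ph(dic, h, k1, k2, kb, kw, bt):
    denom = h * h + k1 * h + k1 * k2
    hco3 = dic * k1 * h / denom
    co3 = dic * k1 * k2 / denom
    return hco3 + 2.0 * co3 + bt * kb / (kb + h) + kw / h - h


def solve(ta_umol, ph, temp_c, sal):
    """Return (pCO2 uatm, DIC umol/kg) for TA (umol/kg) and total-scale pH."""
    k0, k1, k2, kb, kw, bt = constants(temp_c, sal)
    h = 10.0 ** -ph
    ta = ta_umol * 1e-6
    f = lambda dic: ta_from_dic_ph(dic, h, k1, k2, kb, kw, bt) - ta
    dic = brentq(f, 1e-9, 0.02, xtol=1e-18)
    denom = h * h + k1 * h + k1 * k2
    co2 = dic * h * h / denom
    return co2 / k0 * 1e6, dic * 1e6


def main():
    rows = ["ta,ph,temp,salinity,pco2,dic"]
    for ta, ph, t, s in itertools.product(
        (2000.0, 2250.0, 2500.0),
        (7.7, 8.0, 8.3),
        (8.0, 14.0, 20.0),
        (30.0, 34.0, 38.0),
    ):
        pco2, dic = solve(ta, ph, t, s)
        rows.append(f"{ta},{ph},{t},{s},{pco2:.6f},{dic:.6f}")
    out = "tests/testthat/fixtures/carbonate-reference-grid.csv"
    with open(out, "w") as fh:
        fh.write("\n".join(rows) + "\n")
    print(f"wrote {out} ({len(rows) - 1} rows)")


if __name__ == "__main__":
    main()
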
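{
  "81": {
    "smiles": "CCCCOCCO",
    "state": "complete",
    "name": "2-butoxyethanol (synthetic example)",
    "source": "synthetic example record illustrating the record layout",
    "figure": "1",
    "method": "F",
    "type": "nonionic",
    "solvent": "water",
    "labels": [
      ["L_1", "L1"],
      ["L_1 + W", "L1+W"],
      ["L_α", "La"]
    ],
    "keys": ["temperature", "composition", "L1", "L1+W", "La"],
    "values": [
      [0, 0, 0, 20, 20, 20, 40, 40, 40],
      [0, 50, 100, 0, 50, 100, 0, 50, 100],
      [100, 50, 0, 33.3333333333333, 0, 0, 0, 0, 0],
      [0, 50, 100, 33.3333333333333, 50, 10, 50, 20, 0],
      [0, 0, 0, 33.3333333333333, 50, 90, 50, 80, 100]
    ]
  }
}
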
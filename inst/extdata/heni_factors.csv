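risk,factor,intake_unit
Calcium,-5.1000,g
Polyunsaturated fatty acids,-0.6000,g
Sodium,13.9000,g
Trans fats,4.4000,g
Whole grains,-0.3400,g
Nuts and seeds,-1.5000,g
Legumes,-0.2300,g
Vegetables,-0.0830,g
Fruits,-0.1800,g
Seafood,-81.000,g
Processed meats,0.8600,g
Red meats,0.0990,g
Milk,-0.0077,g
Fiber,-0.1900,g
Sugar-sweetened beverages,0.0660,g
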